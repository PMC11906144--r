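"""Molecular featurization helper backed by RDKit.

Reads a CSV with columns molecule_id,smiles and writes a CSV of the
requested descriptor block. Invoked by the R package as a subprocess;
all output is deterministic for a given input and task.

Tasks:
  validate  -> molecule_id, canonical_smiles, ok, error
  physchem  -> molecule_id + one column per RDKit 2D descriptor
  morgan    -> molecule_id + morgan_0001..morgan_NNNN   (binary)
  rdkitfp   -> molecule_id + rdkfp_0001..rdkfp_2048     (binary)
  maccs     -> molecule_id + maccs_001..maccs_166       (binary)

Morgan fingerprints are computed with includeChirality=True so that
enantiomers encoded by isomeric SMILES receive distinct bit rows; the
generator default would collapse them.
MACCS keys: RDKit returns 167 bits with a dummy leading bit 0, which is
dropped so rows expose exactly the 166 substructure keys.
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, MACCSkeys
from rdkit.Chem import rdFingerprintGenerator as rfg

RDLogger.DisableLog("rdApp.*")


def read_input(path):
    with open(path, newline="") as fh:
        rows = list(csv.DictReader(fh))
    for r in rows:
        if "molecule_id" not in r or "smiles" not in r:
            sys.exit("input CSV must have columns molecule_id,smiles")
    return rows


def parse_all(rows):
    out = []
    for r in rows:
        mol = Chem.MolFromSmiles(r["smiles"])
        out.append((r["molecule_id"], r["smiles"], mol))
    return out


def task_validate(parsed, writer):
    writer.writerow(["molecule_id", "canonical_smiles", "ok", "error"])
    for mid, smi, mol in parsed:
        if mol is None:
            writer.writerow([mid, "", 0, "unparsable SMILES"])
        else:
            writer.writerow([mid, Chem.MolToSmiles(mol), 1, ""])


def require_parsed(parsed):
    bad = [mid for mid, _, mol in parsed if mol is None]
    if bad:
        sys.exit("unparsable SMILES for: " + ", ".join(bad))


def task_physchem(parsed, writer):
    require_parsed(parsed)
    names = [n for n, _ in Descriptors._descList]
    writer.writerow(["molecule_id"] + names)
    for mid, _, mol in parsed:
        vals = Descriptors.CalcMolDescriptors(mol)
        writer.writerow([mid] + [repr(float(vals[n])) for n in names])


def write_bits(parsed, writer, gen, prefix, nbits, drop_first=False):
    require_parsed(parsed)
    width = len(str(nbits))
    writer.writerow(
        ["molecule_id"] + [f"{prefix}_{i + 1:0{width}d}" for i in range(nbits)]
    )
    for mid, _, mol in parsed:
        bits = list(gen(mol))
        if drop_first:
            bits = bits[1:]
        assert len(bits) == nbits
        writer.writerow([mid] + bits)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--task", required=True,
                    choices=["validate", "physchem", "morgan", "rdkitfp", "maccs"])
    ap.add_argument("--input", required=True)
    ap.add_argument("--output", required=True)
    ap.add_argument("--n-bits", type=int, default=2048)
    ap.add_argument("--radius", type=int, default=2)
    args = ap.parse_args()

    if args.task == "morgan" and args.n_bits <= 0:
        sys.exit("n_bits must be positive")
    if args.task == "morgan" and args.radius < 0:
        sys.exit("radius must be non-negative")

    parsed = parse_all(read_input(args.input))
    with open(args.output, "w", newline="") as fh:
        writer = csv.writer(fh)
        if args.task == "validate":
            task_validate(parsed, writer)
        elif args.task == "physchem":
            task_physchem(parsed, writer)
        elif args.task == "morgan":
            gen = rfg.GetMorganGenerator(
                radius=args.radius, fpSize=args.n_bits, includeChirality=True
            )
            write_bits(parsed, writer, gen.GetFingerprint, "morgan", args.n_bits)
        elif args.task == "rdkitfp":
            gen = rfg.GetRDKitFPGenerator()
            write_bits(parsed, writer, gen.GetFingerprint, "rdkfp", 2048)
        elif args.task == "maccs":
            write_bits(parsed, writer, MACCSkeys.GenMACCSKeys, "maccs", 166,
                       drop_first=True)


if __name__ == "__main__":
    main()
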