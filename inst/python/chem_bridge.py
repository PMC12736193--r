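#!/usr/bin/env python
"""Batched SMILES services over stdin/stdout.

Usage: python chem_bridge.py <op>
  op = check : one SMILES per input line -> "<valid>\t<canonical>"
  op = full  : one SMILES per input line -> "<valid>\t<canonical>\t<qed>\t<fp-bits>"

valid is 0/1 (sanitizing parse; the empty string counts as invalid),
canonical is the toolkit canonical SMILES ("" when invalid),
qed is the quantitative estimate of drug-likeness ("" when invalid),
fp-bits is a comma-separated list of set bit indices (0-based) of the
radius-2, 2048-bit Morgan fingerprint ("" when invalid; "-" when valid
but no bits set).

Input lines are taken verbatim (SMILES cannot contain whitespace).
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, QED

RDLogger.DisableLog("rdApp.*")


def parse(s):
    if s == "":
        return None
    try:
        return Chem.MolFromSmiles(s)
    except Exception:
        return None


def main():
    op = sys.argv[1] if len(sys.argv) > 1 else "check"
    out = sys.stdout
    for line in sys.stdin:
        s = line.rstrip("\n").rstrip("\r")
        mol = parse(s)
        if mol is None:
            row = ["0", ""] if op == "check" else ["0", "", "", ""]
            out.write("\t".join(row) + "\n")
            continue
        can = Chem.MolToSmiles(mol)
        if op == "check":
            out.write("1\t%s\n" % can)
            continue
        try:
            q = "%.10f" % QED.qed(mol)
        except Exception:
            q = ""
        fp = AllChem.GetMorganFingerprintAsBitVect(mol, 2, nBits=2048)
        bits = list(fp.GetOnBits())
        bstr = ",".join(str(b) for b in bits) if bits else "-"
        out.write("1\t%s\t%s\t%s\n" % (can, q, bstr))
    out.flush()


if __name__ == "__main__":
    main()
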