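"""Batched RDKit backend for pkaladder.

Reads one JSON request on stdin:

    {"smiles": [...],
     "want": ["inchi", "heavy", "fp"],      # any subset
     "fp_radius": 4, "fp_bits": 2048,       # optional, defaults shown
     "smarts": [{"name": ..., "pattern": ...}, ...]}   # optional

and writes a JSON list with one record per input structure:

    {"ok": true, "inchi": ..., "heavy_atoms": ..., "fp_bits": [...],
     "matches": {"name": count, ...}}

Unparseable SMILES give {"ok": false}; an invalid SMARTS pattern is a
configuration error and exits with status 2 before any structure is
processed.
"""

import json
import sys


def main():
    req = json.load(sys.stdin)

    from rdkit import Chem, RDLogger

    RDLogger.DisableLog("rdApp.*")

    want = set(req.get("want", []))
    patterns = []
    for spec in req.get("smarts", []) or []:
        query = Chem.MolFromSmarts(spec["pattern"])
        if query is None:
            sys.stderr.write("invalid SMARTS pattern: %s\n" % spec["pattern"])
            sys.exit(2)
        patterns.append((spec["name"], query))

    fp_gen = None
    if "fp" in want:
        from rdkit.Chem import rdFingerprintGenerator

        fp_gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=int(req.get("fp_radius", 4)),
            fpSize=int(req.get("fp_bits", 2048)),
        )

    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False})
            continue
        rec = {"ok": True}
        if "inchi" in want:
            flat = Chem.Mol(mol)
            Chem.RemoveStereochemistry(flat)
            inchi = Chem.MolToInchi(flat)
            if inchi is None or inchi == "":
                out.append({"ok": False})
                continue
            rec["inchi"] = inchi
        if "heavy" in want:
            rec["heavy_atoms"] = mol.GetNumHeavyAtoms()
        if fp_gen is not None:
            rec["fp_bits"] = list(fp_gen.GetFingerprint(mol).GetOnBits())
        if patterns:
            rec["matches"] = {
                name: len(mol.GetSubstructMatches(query)) for name, query in patterns
            }
        out.append(rec)

    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
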