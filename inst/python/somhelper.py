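"""Chemistry back end for the somannot R package.

Batch-oriented subprocess helper built on RDKit. The R side never parses
chemistry itself: it sends SMILES in bulk and receives standardized
molecular graphs (atoms, kekule bond orders + aromatic flags, InChI keys)
as JSON, with atoms renumbered into canonical-SMILES output order so that
re-parsing the emitted canonical SMILES reproduces the same atom indexing.

Subcommands:
  standardize IN.tsv OUT.json   -- IN: <id>\t<smiles> per line
  write_sdf   SPEC.json         -- SPEC: {"path":..., "records":[{"smiles":...,
                                   "name":..., "props":{...}}, ...]}
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

_NORMALIZER = rdMolStandardize.Normalizer()
_UNCHARGER = rdMolStandardize.Uncharger()
_TAUTOMER = rdMolStandardize.TautomerEnumerator()


def _largest_organic_fragment(mol):
    """Keep one parent component: organic fragments first, then most heavy
    atoms, ties broken by lexicographically smallest InChI key."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return mol

    def key(frag):
        has_c = any(a.GetSymbol() == "C" for a in frag.GetAtoms())
        try:
            ik = Chem.MolToInchiKey(frag) or "~"
        except Exception:
            ik = "~"
        return (0 if has_c else 1, -frag.GetNumHeavyAtoms(), ik)

    return sorted(frags, key=key)[0]


def _recombine_hypervalent(mol):
    """Collapse charge-separated [S+]-[O-] / [P+]-[O-] to the neutral
    hypervalent form (sulfoxides, phosphine oxides), so formal charges
    compare consistently across substrate and metabolite."""
    rw = Chem.RWMol(mol)
    changed = False
    for b in rw.GetBonds():
        a1, a2 = b.GetBeginAtom(), b.GetEndAtom()
        if a1.GetSymbol() == "O":
            a1, a2 = a2, a1
        if (
            a1.GetSymbol() in ("S", "P")
            and a1.GetFormalCharge() == 1
            and a2.GetSymbol() == "O"
            and a2.GetFormalCharge() == -1
            and b.GetBondType() == Chem.BondType.SINGLE
        ):
            b.SetBondType(Chem.BondType.DOUBLE)
            a1.SetFormalCharge(0)
            a2.SetFormalCharge(0)
            changed = True
    if not changed:
        return mol
    out = rw.GetMol()
    Chem.SanitizeMol(out)
    return out


def _standardize_one(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None, "unparseable"
    try:
        mol = Chem.RemoveHs(mol)
        mol = _largest_organic_fragment(mol)
        # normalization transforms may drop atom-map anchors; they preserve
        # atom order, so snapshot and restore the maps by index
        maps = [a.GetAtomMapNum() for a in mol.GetAtoms()]
        mol = _NORMALIZER.normalize(mol)
        mol = _UNCHARGER.uncharge(mol)
        mol = _recombine_hypervalent(mol)
        mol = _TAUTOMER.Canonicalize(mol)
        Chem.SanitizeMol(mol)
        if mol.GetNumAtoms() == len(maps):
            for a, mnum in zip(mol.GetAtoms(), maps):
                a.SetAtomMapNum(mnum)
    except Exception:
        return None, "unparseable"
    return mol, None


def _emit(mol):
    """Serialize a standardized mol, renumbered into canonical SMILES order."""
    plain = Chem.Mol(mol)
    for a in plain.GetAtoms():
        a.SetAtomMapNum(0)
    try:
        inchikey = Chem.MolToInchiKey(plain)
    except Exception:
        inchikey = ""
    if not inchikey:
        return None, "key_failure"
    smiles = Chem.MolToSmiles(plain)
    order = list(
        map(int, plain.GetProp("_smilesAtomOutputOrder")[1:-1].split(","))
    )
    mol = Chem.RenumberAtoms(mol, order)

    kek = Chem.Mol(mol)
    Chem.Kekulize(kek, clearAromaticFlags=False)
    atoms = [
        {
            "el": a.GetSymbol(),
            "chg": a.GetFormalCharge(),
            "nh": a.GetTotalNumHs(),
            "arom": a.GetIsAromatic(),
            "ring": a.IsInRing(),
            "map": a.GetAtomMapNum(),
        }
        for a in kek.GetAtoms()
    ]
    bonds = [
        {
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "order": int(b.GetBondTypeAsDouble()),
            "arom": b.GetIsAromatic(),
            "ring": b.IsInRing(),
        }
        for b in kek.GetBonds()
    ]
    return {
        "atoms": atoms,
        "bonds": bonds,
        "inchikey": inchikey,
        "smiles": smiles,
    }, None


def cmd_standardize(path_in, path_out):
    out = []
    with open(path_in, encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            mol, err = _standardize_one(smiles)
            if mol is None:
                out.append({"id": ident, "ok": False, "error": err})
                continue
            rec, err = _emit(mol)
            if rec is None:
                out.append({"id": ident, "ok": False, "error": err})
                continue
            rec.update({"id": ident, "ok": True})
            out.append(rec)
    with open(path_out, "w", encoding="utf-8") as fh:
        json.dump(out, fh)


def cmd_write_sdf(spec_path):
    with open(spec_path, encoding="utf-8") as fh:
        spec = json.load(fh)
    writer = Chem.SDWriter(spec["path"])
    writer.SetKekulize(True)
    for rec in spec["records"]:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            continue
        AllChem.Compute2DCoords(mol)
        mol.SetProp("_Name", str(rec.get("name", "")))
        for key, value in rec.get("props", {}).items():
            mol.SetProp(key, str(value))
        writer.write(mol)
    writer.close()


def main(argv):
    cmd = argv[1]
    if cmd == "standardize":
        cmd_standardize(argv[2], argv[3])
    elif cmd == "write_sdf":
        cmd_write_sdf(argv[2])
    else:
        raise SystemExit(f"unknown subcommand: {cmd}")


if __name__ == "__main__":
    main(sys.argv)
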