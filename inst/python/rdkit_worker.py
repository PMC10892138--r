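"""Long-running RDKit worker.

Reads JSON-lines requests from one named pipe and writes JSON-lines
responses to another.  One worker serves one R session; it exits when the
request pipe reaches EOF (i.e. when the R side closes its connection).

Request:  {"id": <int>, "op": "ping"|"props"|"randomize", ...}
Response: {"id": <int>, "ok": true, ...} or {"id": <int>, "ok": false,
           "error": "<message>"}
"""

import json
import random
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski, QED

RDLogger.DisableLog("rdApp.*")


def mol_props(smiles):
    """Validity plus the descriptor set used for RO5 and reporting.

    A SMILES is valid iff it is non-empty, has no whitespace, and parses to
    a molecule with at least one atom under default sanitization.
    """
    out = {"smiles": smiles, "valid": False, "canonical": None, "qed": None,
           "mw": None, "logp": None, "hbd": None, "hba": None,
           "rotatable_bonds": None, "rings": None}
    if not smiles or any(ch.isspace() for ch in smiles):
        return out
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        return out
    try:
        out.update({
            "valid": True,
            "canonical": Chem.MolToSmiles(mol),
            "qed": QED.qed(mol),
            "mw": Descriptors.MolWt(mol),
            "logp": Crippen.MolLogP(mol),
            # Lipinski's original definitions: OH+NH donors, N+O acceptors
            "hbd": Lipinski.NHOHCount(mol),
            "hba": Lipinski.NOCount(mol),
            "rotatable_bonds": Lipinski.NumRotatableBonds(mol),
            "rings": Descriptors.RingCount(mol),
        })
    except Exception:
        out["valid"] = False
    return out


def randomize_smiles(smiles, seed):
    """A non-canonical SMILES of the same molecule via atom renumbering."""
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("invalid SMILES: %r" % smiles)
    order = list(range(mol.GetNumAtoms()))
    random.Random(seed).shuffle(order)
    mol = Chem.RenumberAtoms(mol, order)
    return Chem.MolToSmiles(mol, canonical=False)


def handle(req):
    op = req.get("op")
    if op == "ping":
        return {"pong": True}
    if op == "props":
        return {"results": [mol_props(s) for s in req["smiles"]]}
    if op == "randomize":
        return {"smiles": randomize_smiles(req["smiles"], int(req["seed"]))}
    raise ValueError("unknown op: %r" % op)


def main(in_path, out_path):
    # Open order matters with fifos: the R side opens its write end first,
    # then its read end; mirror that here to avoid a deadlock.
    inp = open(in_path, "r")
    out = open(out_path, "w")
    for line in inp:
        line = line.strip()
        if not line:
            continue
        req = json.loads(line)
        try:
            resp = {"id": req.get("id"), "ok": True}
            resp.update(handle(req))
        except Exception as exc:  # report, never die mid-session
            resp = {"id": req.get("id"), "ok": False, "error": str(exc)}
        out.write(json.dumps(resp) + "\n")
        out.flush()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
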