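"""Batched chemistry / QSAR operations for the condsmiles R package.

Usage: python chem_ops.py <op> <input.json> <output.json>

The R side writes a JSON request, invokes this script once per batch, and
reads the JSON reply.  Large numeric matrices travel as CSV side files whose
paths are given in the request, never inline in JSON.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, BRICS, Crippen, Descriptors, MACCSkeys, QED, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonicalize(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": out}


def op_brics(req):
    frags = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            frags.append([])
        else:
            frags.append(sorted(BRICS.BRICSDecompose(m)))
    return {"fragments": frags}


def op_morgan(req):
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 1024))
    use_features = bool(req.get("use_features", False))
    bits = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            bits.append(None)
        else:
            fp = AllChem.GetMorganFingerprintAsBitVect(
                m, radius, nBits=n_bits, useFeatures=use_features)
            bits.append(sorted(fp.GetOnBits()))
    return {"bits": bits, "n_bits": n_bits}


def op_maccs(req):
    # MACCS keys are 167 bits with bit 0 unused; report 0-based 0..165.
    bits = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            bits.append(None)
        else:
            on = [b - 1 for b in MACCSkeys.GenMACCSKeys(m).GetOnBits() if b >= 1]
            bits.append(on)
    return {"bits": bits, "n_bits": 166}


def op_props(req):
    cols = {k: [] for k in ("mw", "tpsa", "logp", "hbd", "hba", "qed", "sa")}
    sascorer = _load_sascorer()
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            for k in cols:
                cols[k].append(None)
            continue
        cols["mw"].append(Descriptors.MolWt(m))
        cols["tpsa"].append(rdMolDescriptors.CalcTPSA(m))
        cols["logp"].append(Crippen.MolLogP(m))
        cols["hbd"].append(rdMolDescriptors.CalcNumHBD(m))
        cols["hba"].append(rdMolDescriptors.CalcNumHBA(m))
        cols["qed"].append(QED.qed(m))
        cols["sa"].append(sascorer.calculateScore(m))
    return cols


def _load_sascorer():
    import os
    from rdkit.Chem import RDConfig
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer
    return sascorer


def op_substruct(req):
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        raise ValueError("bad SMARTS: %r" % req["smarts"])
    match = []
    for smi in req["smiles"]:
        m = _mol(smi)
        match.append(bool(m is not None and m.HasSubstructMatch(patt)))
    return {"match": match}


def op_descriptors(req):
    """Full alphabetized RDKit descriptor block, NaN/inf imputed to 0."""
    import math
    desc = sorted(Descriptors._descList, key=lambda t: t[0])
    names = [n for n, _ in desc]
    rows = []
    n_imputed = 0
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            rows.append(None)
            continue
        row = []
        for _, fn in desc:
            try:
                v = float(fn(m))
            except Exception:
                v = float("nan")
            if not math.isfinite(v):
                v = 0.0
                n_imputed += 1
            row.append(v)
        rows.append(row)
    return {"names": names, "values": rows, "n_imputed": n_imputed}


def op_featurize(req):
    """FCFP6 (2048) + MACCS (166) + descriptor block padded to fixed width.

    Writes the dense n x p matrix to req['out_csv'] (no header); the reply
    carries only metadata.
    """
    import math

    import numpy as np

    desc = sorted(Descriptors._descList, key=lambda t: t[0])
    n_desc_slots = int(req.get("n_desc_slots", 319))
    if len(desc) > n_desc_slots:
        desc = desc[:n_desc_slots]
    names = [n for n, _ in desc]
    smiles = req["smiles"]
    p = 2048 + 166 + n_desc_slots
    x = np.zeros((len(smiles), p), dtype=np.float64)
    bad = []
    n_imputed = 0
    for i, smi in enumerate(smiles):
        m = _mol(smi)
        if m is None:
            bad.append(i)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(m, 3, nBits=2048, useFeatures=True)
        for b in fp.GetOnBits():
            x[i, b] = 1.0
        for b in MACCSkeys.GenMACCSKeys(m).GetOnBits():
            if b >= 1:
                x[i, 2048 + b - 1] = 1.0
        for j, (_, fn) in enumerate(desc):
            try:
                v = float(fn(m))
            except Exception:
                v = float("nan")
            if not math.isfinite(v):
                v = 0.0
                n_imputed += 1
            x[i, 2048 + 166 + j] = v
    import pandas as pd
    pd.DataFrame(x).to_csv(req["out_csv"], header=False, index=False)
    return {"n": len(smiles), "p": p, "desc_names": names,
            "n_desc_slots": n_desc_slots, "bad_rows": bad, "n_imputed": n_imputed}


def op_qsar_fit(req):
    """Fit a histogram gradient-boosted regression tree model (LightGBM-style)."""
    import joblib
    import numpy as np
    import pandas as pd
    from sklearn.ensemble import HistGradientBoostingRegressor

    x = pd.read_csv(req["x_csv"], header=None).to_numpy(dtype=np.float64)
    y = np.asarray(req["y"], dtype=np.float64)
    model = HistGradientBoostingRegressor(
        random_state=int(req.get("seed", 0)),
        max_iter=int(req.get("max_iter", 300)),
        learning_rate=float(req.get("learning_rate", 0.1)),
        early_stopping=True,
        validation_fraction=0.1,
    )
    model.fit(x, y)
    joblib.dump(model, req["model_path"])
    pred_train = model.predict(x).tolist()
    return {"ok": True, "n_iter": int(model.n_iter_), "pred_train": pred_train}


def op_qsar_predict(req):
    import joblib
    import numpy as np
    import pandas as pd

    model = joblib.load(req["model_path"])
    x = pd.read_csv(req["x_csv"], header=None).to_numpy(dtype=np.float64)
    return {"pred": model.predict(x).tolist()}


OPS = {
    "canonicalize": op_canonicalize,
    "brics": op_brics,
    "morgan": op_morgan,
    "maccs": op_maccs,
    "props": op_props,
    "substruct": op_substruct,
    "descriptors": op_descriptors,
    "featurize": op_featurize,
    "qsar_fit": op_qsar_fit,
    "qsar_predict": op_qsar_predict,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chem_ops.py <op> <input.json> <output.json>\n")
        return 2
    op, in_path, out_path = argv[1], argv[2], argv[3]
    if op not in OPS:
        sys.stderr.write("unknown op: %s\n" % op)
        return 2
    with open(in_path) as fh:
        req = json.load(fh)
    res = OPS[op](req)
    with open(out_path, "w") as fh:
        json.dump(res, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
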