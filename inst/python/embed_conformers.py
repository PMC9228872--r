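"""Distance-geometry conformer embedding helper.

Reads a single-record SDF (explicit hydrogens, any or zero coordinates),
embeds up to N conformers with seeded ETKDG distance geometry, relaxes them
with MMFF94 and writes a multi-record SDF preserving the input atom order.

Usage: python embed_conformers.py in.sdf out.sdf max_confs seed
Exit status 3 flags an embedding failure (no conformers).
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    inp, out, n, seed = sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4])
    block = open(inp).read()
    mol = Chem.MolFromMolBlock(block, removeHs=False, sanitize=True)
    if mol is None:
        return 3
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.pruneRmsThresh = 0.5
    params.useRandomCoords = False
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=n, params=params)
    if len(ids) == 0:
        return 3
    try:
        AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=500)
    except Exception:
        pass  # unrelaxed geometry is still usable
    with Chem.SDWriter(out) as w:
        for cid in ids:
            w.write(mol, confId=cid)
    return 0


if __name__ == "__main__":
    sys.exit(main())
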