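"""Convert between AnnData .h5ad files and a plain-text mtx directory.

Used by the R package through system2(); the directory layout matches its
native MatrixMarket reader: matrix.mtx (genes x cells), genes.tsv, cells.tsv.
"""

import sys

import numpy as np
import pandas as pd
import scipy.io
import scipy.sparse
import anndata as ad


def export(h5ad_path, outdir, cell_type_col, condition_col):
    adata = ad.read_h5ad(h5ad_path)
    for col in (cell_type_col, condition_col):
        if col not in adata.obs.columns:
            sys.exit(f"annotation column '{col}' missing from obs")
    x = adata.X
    if scipy.sparse.issparse(x):
        x = x.tocsr()
    else:
        x = scipy.sparse.csr_matrix(np.asarray(x))
    scipy.io.mmwrite(f"{outdir}/matrix.mtx", x.T)
    with open(f"{outdir}/genes.tsv", "w") as fh:
        fh.write("\n".join(map(str, adata.var_names)) + "\n")
    cells = pd.DataFrame(
        {
            "cell_id": adata.obs_names,
            cell_type_col: adata.obs[cell_type_col].astype(str),
            condition_col: adata.obs[condition_col].astype(str),
        }
    )
    cells.to_csv(f"{outdir}/cells.tsv", sep="\t", index=False)


def import_(indir, h5ad_path, cell_type_col, condition_col):
    m = scipy.io.mmread(f"{indir}/matrix.mtx").tocsr().T.tocsr()
    genes = [line.strip() for line in open(f"{indir}/genes.tsv") if line.strip()]
    cells = pd.read_csv(f"{indir}/cells.tsv", sep="\t", dtype=str)
    adata = ad.AnnData(
        X=m.astype(np.float64),
        obs=pd.DataFrame(
            {
                cell_type_col: cells[cell_type_col].values,
                condition_col: cells[condition_col].values,
            },
            index=cells.iloc[:, 0].values,
        ),
        var=pd.DataFrame(index=genes),
    )
    adata.write_h5ad(h5ad_path)


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "export":
        export(*sys.argv[2:6])
    elif mode == "import":
        import_(*sys.argv[2:6])
    else:
        sys.exit(f"unknown mode: {mode}")
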