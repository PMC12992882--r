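#!/usr/bin/env python
"""Independent reference implementation of the standardized radiomics
definitions, used only as a cross-check oracle by the test suite.

Reads a NIfTI image and binary mask, computes 3D shape features (marching
cubes via scikit-image + trimesh + scipy convex hulls), first-order
features (numpy) and co-occurrence features (explicit per-voxel pair
enumeration), and prints them as JSON.

usage: radiomics_oracle.py IMAGE.nii.gz MASK.nii.gz [n_bins]
"""
import json
import sys

import nibabel as nib
import numpy as np
from scipy.spatial import ConvexHull
from skimage import measure
import trimesh


def shape_features(mask, spacing):
    padded = np.pad(mask, 1).astype(float)
    verts, faces, _, _ = measure.marching_cubes(padded, level=0.5, method="lorensen")
    verts = verts * np.asarray(spacing)
    tm = trimesh.Trimesh(verts, faces, process=False)
    area = float(tm.area)
    vol = float(abs(tm.volume))
    out = {
        "MeshVolume": vol,
        "VoxelVolume": float(mask.sum() * np.prod(spacing)),
        "SurfaceArea": area,
        "SurfaceVolumeRatio": area / vol,
        "Sphericity": (36 * np.pi * vol ** 2) ** (1 / 3) / area,
    }
    pts = np.unique(verts, axis=0)
    hull = pts[ConvexHull(pts).vertices] if len(pts) > 4 else pts
    d2 = ((hull[:, None, :] - hull[None, :, :]) ** 2).sum(-1)
    out["Maximum3DDiameter"] = float(np.sqrt(d2.max()))
    planes = {"Maximum2DDiameterSlice": (0, 1),
              "Maximum2DDiameterColumn": (0, 2),
              "Maximum2DDiameterRow": (1, 2)}
    for name, (a, b) in planes.items():
        p2 = np.unique(pts[:, [a, b]], axis=0)
        if len(p2) > 4:
            p2 = p2[ConvexHull(p2).vertices]
        dd = ((p2[:, None, :] - p2[None, :, :]) ** 2).sum(-1)
        out[name] = float(np.sqrt(dd.max()))
    coords = np.argwhere(mask > 0) * np.asarray(spacing)
    ev = np.sort(np.linalg.eigvalsh(np.cov(coords.T)))[::-1]
    ev = np.clip(ev, 0, None)
    out["MajorAxisLength"] = float(4 * np.sqrt(ev[0]))
    out["MinorAxisLength"] = float(4 * np.sqrt(ev[1]))
    out["LeastAxisLength"] = float(4 * np.sqrt(ev[2]))
    out["Elongation"] = float(np.sqrt(ev[1] / ev[0]))
    out["Flatness"] = float(np.sqrt(ev[2] / ev[0]))
    return out


def discretize(vals, n_bins):
    lo, hi = vals.min(), vals.max()
    if hi == lo:
        return np.ones(len(vals), dtype=int)
    w = (hi - lo) / n_bins
    return np.minimum(np.floor((vals - lo) / w).astype(int) + 1, n_bins)


def firstorder(img, mask, spacing, n_bins):
    x = img[mask > 0].astype(float)
    n = x.size
    m = x.mean()
    var = ((x - m) ** 2).mean()
    q10, q25, q75, q90 = np.percentile(x, [10, 25, 75, 90])
    inner = x[(x >= q10) & (x <= q90)]
    lev = discretize(x, n_bins)
    p = np.bincount(lev)[1:] / n
    p = p[p > 0]
    return {
        "Mean": m,
        "Median": float(np.median(x)),
        "P10": q10, "P90": q90,
        "Minimum": x.min(), "Maximum": x.max(),
        "Range": x.max() - x.min(),
        "InterquartileRange": q75 - q25,
        "Variance": var,
        "Skewness": ((x - m) ** 3).mean() / var ** 1.5 if var > 0 else 0.0,
        "Kurtosis": ((x - m) ** 4).mean() / var ** 2 if var > 0 else 0.0,
        "Energy": float((x ** 2).sum()),
        "TotalEnergy": float(np.prod(spacing) * (x ** 2).sum()),
        "RootMeanSquared": float(np.sqrt((x ** 2).mean())),
        "MeanAbsoluteDeviation": float(np.abs(x - m).mean()),
        "RobustMeanAbsoluteDeviation": float(np.abs(inner - inner.mean()).mean()),
        "Entropy": float(-(p * np.log2(p)).sum()),
        "Uniformity": float((p ** 2).sum()),
    }


DIRS = [(dx, dy, dz)
        for dx in (-1, 0, 1) for dy in (-1, 0, 1) for dz in (-1, 0, 1)
        if (dx, dy, dz) != (0, 0, 0)
        and [c for c in (dx, dy, dz) if c != 0][0] > 0]


def glcm(img, mask, n_bins):
    """Per-voxel pair enumeration (no array shifts), 13 directions."""
    lev = np.zeros(mask.shape, dtype=int)
    idx = np.argwhere(mask > 0)
    lev[mask > 0] = discretize(img[mask > 0].astype(float), n_bins)
    feats = []
    shp = mask.shape
    for d in DIRS:
        P = np.zeros((n_bins, n_bins))
        for (i, j, k) in idx:
            ni, nj, nk = i + d[0], j + d[1], k + d[2]
            if 0 <= ni < shp[0] and 0 <= nj < shp[1] and 0 <= nk < shp[2]:
                if lev[ni, nj, nk] > 0:
                    P[lev[i, j, k] - 1, lev[ni, nj, nk] - 1] += 1
        P = P + P.T
        if P.sum() == 0:
            continue
        P /= P.sum()
        feats.append(glcm_vector(P))
    keys = feats[0].keys()
    return {k: float(np.mean([f[k] for f in feats])) for k in keys}


def glcm_vector(P):
    ng = P.shape[0]
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, ng))
    j = i.T
    px, py = P.sum(1), P.sum(0)
    mux, muy = (i * P).sum(), (j * P).sum()
    sigx = np.sqrt(((i - mux) ** 2 * P).sum())
    sigy = np.sqrt(((j - muy) ** 2 * P).sum())
    kdif = np.arange(0, ng)
    pdif = np.array([P[np.abs(i - j) == k].sum() for k in kdif])
    ksum = np.arange(2, 2 * ng + 1)
    psum = np.array([P[(i + j) == k].sum() for k in ksum])

    def H(p):
        p = p[p > 0]
        return -(p * np.log2(p)).sum()

    pipj = np.outer(px, py)
    nz = (P > 0) & (pipj > 0)
    HXY = H(P.ravel())
    HXY1 = -(P[nz] * np.log2(pipj[nz])).sum()
    HXY2 = H(pipj.ravel())
    da = (kdif * pdif).sum()
    hx, hy = H(px), H(py)
    imc2sq = 1 - np.exp(-2 * (HXY2 - HXY))
    off = i != j
    return {
        "Autocorrelation": (i * j * P).sum(),
        "ClusterProminence": ((i + j - mux - muy) ** 4 * P).sum(),
        "ClusterShade": ((i + j - mux - muy) ** 3 * P).sum(),
        "ClusterTendency": ((i + j - mux - muy) ** 2 * P).sum(),
        "Contrast": ((i - j) ** 2 * P).sum(),
        "Correlation": ((i * j * P).sum() - mux * muy) / (sigx * sigy)
        if sigx > 0 and sigy > 0 else 1.0,
        "DifferenceAverage": da,
        "DifferenceEntropy": H(pdif),
        "DifferenceVariance": ((kdif - da) ** 2 * pdif).sum(),
        "Id": (P / (1 + np.abs(i - j))).sum(),
        "Idm": (P / (1 + (i - j) ** 2)).sum(),
        "Idmn": (P / (1 + ((i - j) / ng) ** 2)).sum(),
        "Idn": (P / (1 + np.abs(i - j) / ng)).sum(),
        "Imc1": (HXY - HXY1) / max(hx, hy) if max(hx, hy) > 0 else 0.0,
        "Imc2": np.sqrt(imc2sq) if imc2sq > 0 else 0.0,
        "InverseVariance": (P[off] / (i - j)[off] ** 2).sum(),
        "JointAverage": mux,
        "JointEnergy": (P ** 2).sum(),
        "JointEntropy": HXY,
        "MaximumProbability": P.max(),
        "SumEntropy": H(psum),
        "SumSquares": ((i - mux) ** 2 * P).sum(),
    }


def main():
    img_path, mask_path = sys.argv[1], sys.argv[2]
    n_bins = int(sys.argv[3]) if len(sys.argv) > 3 else 32
    img_n = nib.load(img_path)
    msk_n = nib.load(mask_path)
    img = np.asarray(img_n.dataobj, dtype=float)
    mask = np.asarray(msk_n.dataobj) > 0
    spacing = img_n.header.get_zooms()[:3]
    out = {
        "shape": shape_features(mask, spacing),
        "firstorder": firstorder(img, mask, spacing, n_bins),
        "glcm": glcm(img, mask, n_bins),
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
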