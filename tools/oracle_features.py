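#!/usr/bin/env python
"""Independent reference implementation of the 107 original radiomics
features, used once to freeze expected values for the oracle-equivalence
tests. Deliberately written as plain loops over voxels/pairs (no reuse of
the R package's vectorized/C++ code paths). Reads the plain-text fixture
volumes produced by tools/make_fixture_lesions.R and writes one CSV of
(feature,value) per lesion.

Conventions implemented (the package's documented contract):
  discretization  level = floor((v - min_in_mask)/25) + 1
  GLCM/GLRLM      13 unique 3-D directions, per-direction features, mean
                  over non-empty directions; GLCM symmetric
  GLSZM           26-connected equal-level zones
  GLDM            dependence = 1 + #26-neighbours with equal level (alpha=0)
  NGTDM           26-neighbourhood mean of in-mask neighbours
  shape mesh      marching tetrahedra (6 tets per cell, diagonal v0-v7,
                  vertices at edge midpoints), level 0.5
  diameters       boundary-voxel centres (6-neighbourhood boundary)
  axis lengths    4*sqrt(eigenvalues of sample covariance of physical
                  voxel-centre coordinates)
"""
import sys
import math
import numpy as np
from scipy import ndimage

BIN_WIDTH = 25.0

DIRS = [(1,0,0),(0,1,0),(0,0,1),
        (1,1,0),(1,-1,0),(1,0,1),(1,0,-1),(0,1,1),(0,1,-1),
        (1,1,1),(1,1,-1),(1,-1,1),(1,-1,-1)]


def read_fixture(stem):
    def read(path):
        with open(path) as fh:
            hdr = fh.readline().split()
            dims = tuple(int(x) for x in hdr[2:5])
            spacing = tuple(float(x) for x in hdr[6:9])
            vals = np.array([float(l) for l in fh if l.strip()])
        # R writes column-major (x fastest)
        return vals.reshape(dims, order="F"), spacing
    vol, spacing = read(stem + "_volume.txt")
    msk, _ = read(stem + "_mask.txt")
    return vol, msk.astype(bool), spacing


def discretize(vol, msk):
    v = vol[msk]
    lev = np.zeros(vol.shape, dtype=int)
    lev[msk] = np.floor((vol[msk] - v.min()) / BIN_WIDTH).astype(int) + 1
    return lev, int(lev.max())


def entropy2(p):
    p = p[p > 0]
    return float(-(p * np.log2(p)).sum())


def firstorder(vol, msk, spacing, out):
    x = vol[msk]
    n = x.size
    vv = spacing[0] * spacing[1] * spacing[2]
    lev, ng = discretize(vol, msk)
    counts = np.bincount(lev[msk], minlength=ng + 1)[1:]
    p = counts / n
    mu = x.mean()
    m2 = ((x - mu) ** 2).mean()
    m3 = ((x - mu) ** 3).mean()
    m4 = ((x - mu) ** 4).mean()
    p10 = np.percentile(x, 10)
    p90 = np.percentile(x, 90)
    sub = x[(x >= p10) & (x <= p90)]
    out["original_firstorder_Energy"] = float((x ** 2).sum())
    out["original_firstorder_TotalEnergy"] = float(vv * (x ** 2).sum())
    out["original_firstorder_Entropy"] = entropy2(p)
    out["original_firstorder_Minimum"] = float(x.min())
    out["original_firstorder_10Percentile"] = float(p10)
    out["original_firstorder_90Percentile"] = float(p90)
    out["original_firstorder_Maximum"] = float(x.max())
    out["original_firstorder_Mean"] = float(mu)
    out["original_firstorder_Median"] = float(np.median(x))
    out["original_firstorder_InterquartileRange"] = float(
        np.percentile(x, 75) - np.percentile(x, 25))
    out["original_firstorder_Range"] = float(x.max() - x.min())
    out["original_firstorder_MeanAbsoluteDeviation"] = float(np.abs(x - mu).mean())
    out["original_firstorder_RobustMeanAbsoluteDeviation"] = float(
        np.abs(sub - sub.mean()).mean()) if sub.size else 0.0
    out["original_firstorder_RootMeanSquared"] = float(math.sqrt((x ** 2).mean()))
    out["original_firstorder_Skewness"] = float(m3 / m2 ** 1.5) if m2 > 0 else 0.0
    out["original_firstorder_Kurtosis"] = float(m4 / m2 ** 2) if m2 > 0 else 0.0
    out["original_firstorder_Variance"] = float(m2)
    out["original_firstorder_Uniformity"] = float((p ** 2).sum())


def glcm_direction(lev, d, ng):
    nx, ny, nz = lev.shape
    P = np.zeros((ng, ng))
    dx, dy, dz = d
    for x in range(nx):
        for y in range(ny):
            for z in range(nz):
                a = lev[x, y, z]
                if a == 0:
                    continue
                x2, y2, z2 = x + dx, y + dy, z + dz
                if not (0 <= x2 < nx and 0 <= y2 < ny and 0 <= z2 < nz):
                    continue
                b = lev[x2, y2, z2]
                if b == 0:
                    continue
                P[a - 1, b - 1] += 1
                P[b - 1, a - 1] += 1
    return P


def glcm_features_one(P):
    ng = P.shape[0]
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, ng))
    j = i.T
    px = P.sum(axis=1)
    py = P.sum(axis=0)
    mux = (px * np.arange(1, ng + 1)).sum()
    muy = (py * np.arange(1, ng + 1)).sum()
    sx = math.sqrt((px * (np.arange(1, ng + 1) - mux) ** 2).sum())
    sy = math.sqrt((py * (np.arange(1, ng + 1) - muy) ** 2).sum())
    kd = np.arange(0, ng)
    pd = np.array([P[np.abs(i - j) == k].sum() for k in kd])
    ks = np.arange(2, 2 * ng + 1)
    ps = np.array([P[(i + j) == k].sum() for k in ks])
    da = (pd * kd).sum()
    hxy = entropy2(P.ravel())
    hx = entropy2(px)
    hy = entropy2(py)
    pxpy = np.outer(px, py)
    ok = (P > 0) & (pxpy > 0)
    hxy1 = float(-(P[ok] * np.log2(pxpy[ok])).sum())
    hxy2 = entropy2(pxpy.ravel())
    imc1 = (hxy - hxy1) / max(hx, hy) if max(hx, hy) > 0 else 0.0
    imc2 = math.sqrt(1 - math.exp(-2 * (hxy2 - hxy))) if hxy2 >= hxy else 0.0
    mcc = 1.0
    if ng > 1 and (px > 0).sum() > 1:
        Q = np.zeros((ng, ng))
        tiny = np.finfo(float).tiny
        for a in range(ng):
            if px[a] <= 0:
                continue
            for b in range(ng):
                s = 0.0
                for k in range(ng):
                    if py[k] > 0:
                        s += P[a, k] * P[b, k] / (px[a] * py[k])
                Q[a, b] = s
        ev = np.sort(np.real(np.linalg.eigvals(Q)))[::-1]
        mcc = math.sqrt(max(ev[1], 0.0)) if ev.size >= 2 else 1.0
    offd = np.abs(i - j) > 0
    f = {}
    f["Autocorrelation"] = (P * i * j).sum()
    f["ClusterProminence"] = (P * (i + j - mux - muy) ** 4).sum()
    f["ClusterShade"] = (P * (i + j - mux - muy) ** 3).sum()
    f["ClusterTendency"] = (P * (i + j - mux - muy) ** 2).sum()
    f["Contrast"] = (P * (i - j) ** 2).sum()
    f["Correlation"] = ((P * i * j).sum() - mux * muy) / (sx * sy) \
        if sx * sy > 0 else 1.0
    f["DifferenceAverage"] = da
    f["DifferenceEntropy"] = entropy2(pd)
    f["DifferenceVariance"] = (pd * (kd - da) ** 2).sum()
    f["Id"] = (P / (1 + np.abs(i - j))).sum()
    f["Idm"] = (P / (1 + (i - j) ** 2)).sum()
    f["Idmn"] = (P / (1 + (i - j) ** 2 / ng ** 2)).sum()
    f["Idn"] = (P / (1 + np.abs(i - j) / ng)).sum()
    f["Imc1"] = imc1
    f["Imc2"] = imc2
    f["InverseVariance"] = (P[offd] / (i - j)[offd] ** 2).sum() if offd.any() else 0.0
    f["JointAverage"] = mux
    f["JointEnergy"] = (P ** 2).sum()
    f["JointEntropy"] = hxy
    f["MCC"] = mcc
    f["MaximumProbability"] = P.max()
    f["SumAverage"] = (ps * ks).sum()
    f["SumEntropy"] = entropy2(ps)
    f["SumSquares"] = (P * (i - mux) ** 2).sum()
    return f


def glcm(lev, ng, out):
    accum = None
    nd = 0
    for d in DIRS:
        P = glcm_direction(lev, d, ng)
        tot = P.sum()
        if tot == 0:
            continue
        f = glcm_features_one(P / tot)
        if accum is None:
            accum = {k: 0.0 for k in f}
        for k, v in f.items():
            accum[k] += v
        nd += 1
    for k in accum:
        out["original_glcm_" + k] = accum[k] / nd


def glrlm_direction(lev, d, ng, maxlen):
    nx, ny, nz = lev.shape
    P = np.zeros((ng, maxlen))
    dx, dy, dz = d
    for x in range(nx):
        for y in range(ny):
            for z in range(nz):
                a = lev[x, y, z]
                if a == 0:
                    continue
                px_, py_, pz_ = x - dx, y - dy, z - dz
                if (0 <= px_ < nx and 0 <= py_ < ny and 0 <= pz_ < nz
                        and lev[px_, py_, pz_] == a):
                    continue
                ln = 1
                cx, cy, cz = x + dx, y + dy, z + dz
                while (0 <= cx < nx and 0 <= cy < ny and 0 <= cz < nz
                       and lev[cx, cy, cz] == a):
                    ln += 1
                    cx += dx; cy += dy; cz += dz
                P[a - 1, ln - 1] += 1
    return P


def rl_style_features(P, np_, kind):
    # shared functional forms of the run-length / size-zone families
    ng, nl = P.shape
    nr = P.sum()
    i = np.arange(1, ng + 1)[:, None] * np.ones((1, nl))
    j = np.ones((ng, 1)) * np.arange(1, nl + 1)[None, :]
    pr = P / nr
    mi = (pr * i).sum()
    mj = (pr * j).sum()
    gl = P.sum(axis=1)
    rl = P.sum(axis=0)
    if kind == "glrlm":
        names = ["ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "GrayLevelVariance", "RunVariance", "RunEntropy",
                 "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                 "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"]
    else:
        names = ["SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
                 "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
                 "SizeZoneNonUniformityNormalized", "ZonePercentage",
                 "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
                 "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"]
    vals = [
        (P / j ** 2).sum() / nr,
        (P * j ** 2).sum() / nr,
        (gl ** 2).sum() / nr,
        (gl ** 2).sum() / nr ** 2,
        (rl ** 2).sum() / nr,
        (rl ** 2).sum() / nr ** 2,
        nr / np_,
        (pr * (i - mi) ** 2).sum(),
        (pr * (j - mj) ** 2).sum(),
        entropy2(pr.ravel()),
        (P / i ** 2).sum() / nr,
        (P * i ** 2).sum() / nr,
        (P / (i ** 2 * j ** 2)).sum() / nr,
        (P * i ** 2 / j ** 2).sum() / nr,
        (P * j ** 2 / i ** 2).sum() / nr,
        (P * i ** 2 * j ** 2).sum() / nr,
    ]
    return dict(zip(names, vals))


def glrlm(lev, ng, np_, out):
    maxlen = max(lev.shape)
    accum = None
    nd = 0
    for d in DIRS:
        P = glrlm_direction(lev, d, ng, maxlen)
        if P.sum() == 0:
            continue
        f = rl_style_features(P, np_, "glrlm")
        if accum is None:
            accum = {k: 0.0 for k in f}
        for k, v in f.items():
            accum[k] += v
        nd += 1
    for k in accum:
        out["original_glrlm_" + k] = accum[k] / nd


def glszm(lev, ng, np_, out):
    struct = np.ones((3, 3, 3), dtype=int)
    zones = []
    for level in range(1, ng + 1):
        lab, nz = ndimage.label(lev == level, structure=struct)
        for z in range(1, nz + 1):
            zones.append((level, int((lab == z).sum())))
    maxsize = max(s for _, s in zones)
    P = np.zeros((ng, maxsize))
    for level, s in zones:
        P[level - 1, s - 1] += 1
    for k, v in rl_style_features(P, np_, "glszm").items():
        out["original_glszm_" + k] = v


def gldm(lev, ng, out):
    nx, ny, nz = lev.shape
    P = np.zeros((ng, 27))
    for x in range(nx):
        for y in range(ny):
            for z in range(nz):
                a = lev[x, y, z]
                if a == 0:
                    continue
                dep = 0
                for dx in (-1, 0, 1):
                    for dy in (-1, 0, 1):
                        for dz in (-1, 0, 1):
                            if dx == dy == dz == 0:
                                continue
                            x2, y2, z2 = x + dx, y + dy, z + dz
                            if not (0 <= x2 < nx and 0 <= y2 < ny and 0 <= z2 < nz):
                                continue
                            if lev[x2, y2, z2] != 0 and abs(lev[x2, y2, z2] - a) <= 0:
                                dep += 1
                P[a - 1, dep] += 1
    ngn, nd = P.shape
    nzs = P.sum()
    i = np.arange(1, ngn + 1)[:, None] * np.ones((1, nd))
    j = np.ones((ngn, 1)) * np.arange(1, nd + 1)[None, :]
    pdm = P / nzs
    mi = (pdm * i).sum()
    mj = (pdm * j).sum()
    gl = P.sum(axis=1)
    dp = P.sum(axis=0)
    out["original_gldm_SmallDependenceEmphasis"] = (P / j ** 2).sum() / nzs
    out["original_gldm_LargeDependenceEmphasis"] = (P * j ** 2).sum() / nzs
    out["original_gldm_GrayLevelNonUniformity"] = (gl ** 2).sum() / nzs
    out["original_gldm_DependenceNonUniformity"] = (dp ** 2).sum() / nzs
    out["original_gldm_DependenceNonUniformityNormalized"] = (dp ** 2).sum() / nzs ** 2
    out["original_gldm_GrayLevelVariance"] = (pdm * (i - mi) ** 2).sum()
    out["original_gldm_DependenceVariance"] = (pdm * (j - mj) ** 2).sum()
    out["original_gldm_DependenceEntropy"] = entropy2(pdm.ravel())
    out["original_gldm_LowGrayLevelEmphasis"] = (P / i ** 2).sum() / nzs
    out["original_gldm_HighGrayLevelEmphasis"] = (P * i ** 2).sum() / nzs
    out["original_gldm_SmallDependenceLowGrayLevelEmphasis"] = \
        (P / (i ** 2 * j ** 2)).sum() / nzs
    out["original_gldm_SmallDependenceHighGrayLevelEmphasis"] = \
        (P * i ** 2 / j ** 2).sum() / nzs
    out["original_gldm_LargeDependenceLowGrayLevelEmphasis"] = \
        (P * j ** 2 / i ** 2).sum() / nzs
    out["original_gldm_LargeDependenceHighGrayLevelEmphasis"] = \
        (P * i ** 2 * j ** 2).sum() / nzs


def ngtdm(lev, ng, out):
    nx, ny, nz = lev.shape
    n = np.zeros(ng)
    s = np.zeros(ng)
    for x in range(nx):
        for y in range(ny):
            for z in range(nz):
                a = lev[x, y, z]
                if a == 0:
                    continue
                tot, cnt = 0.0, 0
                for dx in (-1, 0, 1):
                    for dy in (-1, 0, 1):
                        for dz in (-1, 0, 1):
                            if dx == dy == dz == 0:
                                continue
                            x2, y2, z2 = x + dx, y + dy, z + dz
                            if not (0 <= x2 < nx and 0 <= y2 < ny and 0 <= z2 < nz):
                                continue
                            b = lev[x2, y2, z2]
                            if b != 0:
                                tot += b
                                cnt += 1
                n[a - 1] += 1
                if cnt:
                    s[a - 1] += abs(a - tot / cnt)
    np_ = n.sum()
    p = n / np_
    levs = [a for a in range(ng) if n[a] > 0]
    pssum = sum(p[a] * s[a] for a in levs)
    out["original_ngtdm_Coarseness"] = 1.0 / pssum if pssum > 0 else 1e6
    ngp = len(levs)
    if ngp > 1:
        cc = sum(p[a] * p[b] * ((a + 1) - (b + 1)) ** 2
                 for a in levs for b in levs)
        out["original_ngtdm_Contrast"] = cc / (ngp * (ngp - 1)) * s.sum() / np_
    else:
        out["original_ngtdm_Contrast"] = 0.0
    busy_den = sum(abs((a + 1) * p[a] - (b + 1) * p[b])
                   for a in levs for b in levs)
    out["original_ngtdm_Busyness"] = pssum / busy_den if busy_den > 0 else 0.0
    out["original_ngtdm_Complexity"] = sum(
        abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
        for a in levs for b in levs) / np_
    strength = sum((p[a] + p[b]) * (a - b) ** 2 for a in levs for b in levs)
    out["original_ngtdm_Strength"] = strength / s.sum() if s.sum() > 0 else 0.0


TETS = [(0, 1, 3, 7), (0, 3, 2, 7), (0, 2, 6, 7),
        (0, 6, 4, 7), (0, 4, 5, 7), (0, 5, 1, 7)]


def shape(msk, spacing, out):
    nx, ny, nz = msk.shape
    sx, sy, sz = spacing

    def inside(x, y, z):
        return (0 <= x < nx and 0 <= y < ny and 0 <= z < nz
                and bool(msk[x, y, z]))

    tetvol = sx * sy * sz / 6.0
    frac = {0: 0.0, 1: 0.125, 2: 0.5, 3: 0.875, 4: 1.0}
    area = 0.0
    vol = 0.0
    for z in range(-1, nz):
        for y in range(-1, ny):
            for x in range(-1, nx):
                corners = []
                for b in range(8):
                    cx, cy, cz = x + (b & 1), y + ((b >> 1) & 1), z + ((b >> 2) & 1)
                    corners.append(1 if inside(cx, cy, cz) else 0)
                if not any(corners):
                    continue
                if all(corners):
                    vol += 6 * tetvol
                    continue
                for tet in TETS:
                    ins = [corners[v] for v in tet]
                    nin = sum(ins)
                    vol += frac[nin] * tetvol
                    if nin in (0, 4):
                        continue
                    pts = []
                    for v in tet:
                        pts.append(np.array([
                            (x + (v & 1)) * sx,
                            (y + ((v >> 1) & 1)) * sy,
                            (z + ((v >> 2) & 1)) * sz]))
                    iin = [k for k in range(4) if ins[k]]
                    iout = [k for k in range(4) if not ins[k]]
                    if nin in (1, 3):
                        apex = iin[0] if nin == 1 else iout[0]
                        oth = [k for k in range(4) if k != apex]
                        m = [(pts[apex] + pts[o]) / 2 for o in oth]
                        area += 0.5 * np.linalg.norm(
                            np.cross(m[1] - m[0], m[2] - m[0]))
                    else:
                        a0, a1 = iin
                        b0, b1 = iout
                        quad = [(pts[a0] + pts[b0]) / 2, (pts[a0] + pts[b1]) / 2,
                                (pts[a1] + pts[b1]) / 2, (pts[a1] + pts[b0]) / 2]
                        area += 0.5 * np.linalg.norm(
                            np.cross(quad[1] - quad[0], quad[2] - quad[0]))
                        area += 0.5 * np.linalg.norm(
                            np.cross(quad[2] - quad[0], quad[3] - quad[0]))

    # boundary voxels for diameters
    bnd = []
    for x in range(nx):
        for y in range(ny):
            for z in range(nz):
                if not msk[x, y, z]:
                    continue
                if (x in (0, nx - 1) or y in (0, ny - 1) or z in (0, nz - 1)
                        or not msk[x - 1, y, z] or not msk[x + 1, y, z]
                        or not msk[x, y - 1, z] or not msk[x, y + 1, z]
                        or not msk[x, y, z - 1] or not msk[x, y, z + 1]):
                    bnd.append((x, y, z))
    d3 = dsl = dcol = drow = 0.0
    for a in range(len(bnd)):
        for b in range(a + 1, len(bnd)):
            dx = (bnd[a][0] - bnd[b][0]) * sx
            dy = (bnd[a][1] - bnd[b][1]) * sy
            dz = (bnd[a][2] - bnd[b][2]) * sz
            q = dx * dx + dy * dy + dz * dz
            d3 = max(d3, q)
            if bnd[a][2] == bnd[b][2]:
                dsl = max(dsl, dx * dx + dy * dy)
            if bnd[a][1] == bnd[b][1]:
                dcol = max(dcol, dx * dx + dz * dz)
            if bnd[a][0] == bnd[b][0]:
                drow = max(drow, dy * dy + dz * dz)

    coords = np.argwhere(msk) * np.array(spacing)
    nvox = coords.shape[0]
    ev = np.sort(np.clip(np.linalg.eigvalsh(np.cov(coords.T)), 0, None))[::-1] \
        if nvox >= 2 else np.zeros(3)

    out["original_shape_MeshVolume"] = vol
    out["original_shape_VoxelVolume"] = nvox * sx * sy * sz
    out["original_shape_SurfaceArea"] = area
    out["original_shape_SurfaceVolumeRatio"] = area / vol if vol > 0 else 0.0
    out["original_shape_Sphericity"] = \
        (36 * math.pi * vol ** 2) ** (1 / 3) / area if area > 0 else 0.0
    out["original_shape_Maximum3DDiameter"] = math.sqrt(d3)
    out["original_shape_Maximum2DDiameterSlice"] = math.sqrt(dsl)
    out["original_shape_Maximum2DDiameterColumn"] = math.sqrt(dcol)
    out["original_shape_Maximum2DDiameterRow"] = math.sqrt(drow)
    out["original_shape_MajorAxisLength"] = 4 * math.sqrt(ev[0])
    out["original_shape_MinorAxisLength"] = 4 * math.sqrt(ev[1])
    out["original_shape_LeastAxisLength"] = 4 * math.sqrt(ev[2])
    out["original_shape_Elongation"] = math.sqrt(ev[1] / ev[0]) if ev[0] > 0 else 0.0
    out["original_shape_Flatness"] = math.sqrt(ev[2] / ev[0]) if ev[0] > 0 else 0.0


def main(stem, out_csv):
    vol, msk, spacing = read_fixture(stem)
    out = {}
    shape(msk, spacing, out)
    firstorder(vol, msk, spacing, out)
    lev, ng = discretize(vol, msk)
    np_ = int(msk.sum())
    glcm(lev, ng, out)
    glrlm(lev, ng, np_, out)
    glszm(lev, ng, np_, out)
    gldm(lev, ng, out)
    ngtdm(lev, ng, out)
    assert len(out) == 107, f"expected 107 features, got {len(out)}"
    with open(out_csv, "w") as fh:
        fh.write("feature,value\n")
        for k in sorted(out):
            fh.write(f"{k},{out[k]:.12g}\n")
    print(f"{stem}: wrote {len(out)} features -> {out_csv}")


if __name__ == "__main__":
    for stem in sys.argv[1:]:
        main(stem, stem + "_expected.csv")
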