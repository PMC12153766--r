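#!/usr/bin/env python
"""Independent reference evaluator for multi-object tracking metrics.

Implements the CLEAR-MOT correspondence protocol (persisting matches kept
first, remainder matched by minimum 1-IoU assignment), the identity
metrics (optimal global trajectory bijection) and HOTA (global alignment
score matching, 19 IoU thresholds) directly from their published
definitions, on numpy + scipy.optimize.linear_sum_assignment. Serves as a
cross-check oracle for the R implementation.

Usage: python oracle_mot.py gt.txt result.txt  -> JSON on stdout
"""
import json
import sys

import numpy as np
from scipy.optimize import linear_sum_assignment


def read_mot(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if not line:
                continue
            f = line.split(",")
            rows.append((int(float(f[0])), int(float(f[1])), float(f[2]),
                         float(f[3]), float(f[4]), float(f[5])))
    rows.sort(key=lambda r: (r[0], r[1]))
    return rows


def iou(a, b):
    x1 = max(a[0], b[0])
    y1 = max(a[1], b[1])
    x2 = min(a[0] + a[2], b[0] + b[2])
    y2 = min(a[1] + a[3], b[1] + b[3])
    inter = max(x2 - x1, 0.0) * max(y2 - y1, 0.0)
    return inter / (a[2] * a[3] + b[2] * b[3] - inter)


def by_frame(rows):
    d = {}
    for r in rows:
        d.setdefault(r[0], []).append(r)
    return d


def clear_mot(gt, hyp, thr=0.5):
    G, H = by_frame(gt), by_frame(hyp)
    frames = sorted(set(G) | set(H))
    last = {}
    FP = FN = IDSW = matches = 0
    sum_iou = 0.0
    gt_frames = {}
    gt_matched = {}
    for f in frames:
        g = G.get(f, [])
        h = H.get(f, [])
        for gr in g:
            gt_frames[gr[1]] = gt_frames.get(gr[1], 0) + 1
        hid_index = {r[1]: j for j, r in enumerate(h)}
        pairs = []
        used_g, used_h = set(), set()
        # persisting correspondences first
        for i, gr in enumerate(g):
            prev = last.get(gr[1])
            if prev is None:
                continue
            j = hid_index.get(prev)
            if j is not None and j not in used_h and iou(gr[2:], h[j][2:]) >= thr:
                pairs.append((i, j))
                used_g.add(i)
                used_h.add(j)
        gi = [i for i in range(len(g)) if i not in used_g]
        hj = [j for j in range(len(h)) if j not in used_h]
        if gi and hj:
            ious = np.array([[iou(g[i][2:], h[j][2:]) for j in hj] for i in gi])
            big = 1e6
            cost = np.where(ious >= thr, 1.0 - ious, big)
            ri, cj = linear_sum_assignment(cost)
            for a, b in zip(ri, cj):
                if ious[a, b] >= thr:
                    pairs.append((gi[a], hj[b]))
        for i, j in pairs:
            gid, hid = g[i][1], h[j][1]
            if gid in last and last[gid] != hid:
                IDSW += 1
            last[gid] = hid
            sum_iou += iou(g[i][2:], h[j][2:])
            gt_matched[gid] = gt_matched.get(gid, 0) + 1
        matches += len(pairs)
        FN += len(g) - len(pairs)
        FP += len(h) - len(pairs)
    cov = [gt_matched.get(i, 0) / n for i, n in gt_frames.items()]
    return dict(MOTA=1.0 - (FN + FP + IDSW) / len(gt), FP=FP, FN=FN,
                IDS=IDSW, MOTP=sum_iou / matches if matches else None,
                MT=sum(1 for r in cov if r >= 0.8),
                ML=sum(1 for r in cov if r <= 0.2))


def idf1(gt, hyp, thr=0.5):
    gids = sorted({r[1] for r in gt})
    hids = sorted({r[1] for r in hyp})
    gix = {i: a for a, i in enumerate(gids)}
    hix = {j: b for b, j in enumerate(hids)}
    m = np.zeros((len(gids), len(hids)))
    G, H = by_frame(gt), by_frame(hyp)
    for f in set(G) & set(H):
        for gr in G[f]:
            for hr in H[f]:
                if iou(gr[2:], hr[2:]) >= thr:
                    m[gix[gr[1]], hix[hr[1]]] += 1
    idtp = 0.0
    if len(gids) and len(hids):
        ri, cj = linear_sum_assignment(-m)
        idtp = m[ri, cj].sum()
    idfn = len(gt) - idtp
    idfp = len(hyp) - idtp
    return 2 * idtp / (2 * idtp + idfp + idfn)


def hota(gt, hyp):
    alphas = np.arange(1, 20) * 0.05
    gids = sorted({r[1] for r in gt})
    hids = sorted({r[1] for r in hyp})
    gix = {i: a for a, i in enumerate(gids)}
    hix = {j: b for b, j in enumerate(hids)}
    gt_count = np.zeros(len(gids))
    hyp_count = np.zeros(len(hids))
    for r in gt:
        gt_count[gix[r[1]]] += 1
    for r in hyp:
        hyp_count[hix[r[1]]] += 1
    G, H = by_frame(gt), by_frame(hyp)
    frames = sorted(set(G) | set(H))
    frame_data = []
    potential = np.zeros((len(gids), len(hids)))
    eps = np.finfo(float).eps
    for f in frames:
        g = G.get(f, [])
        h = H.get(f, [])
        gi = np.array([gix[r[1]] for r in g], dtype=int)
        hj = np.array([hix[r[1]] for r in h], dtype=int)
        sim = np.array([[iou(gr[2:], hr[2:]) for hr in h] for gr in g])
        sim = sim.reshape((len(g), len(h)))
        frame_data.append((gi, hj, sim))
        if len(g) and len(h):
            denom = sim.sum(0)[None, :] + sim.sum(1)[:, None] - sim
            soft = np.zeros_like(sim)
            ok = denom > eps
            soft[ok] = sim[ok] / denom[ok]
            potential[np.ix_(gi, hj)] += soft
    align = potential / (gt_count[:, None] + hyp_count[None, :] - potential)
    tp = np.zeros(len(alphas))
    match_count = [np.zeros((len(gids), len(hids))) for _ in alphas]
    for gi, hj, sim in frame_data:
        if not len(gi) or not len(hj):
            continue
        score = align[np.ix_(gi, hj)] * sim
        ri, cj = linear_sum_assignment(-score)
        sims = sim[ri, cj]
        for a, alpha in enumerate(alphas):
            ok = sims >= alpha - eps
            tp[a] += ok.sum()
            for r, c in zip(ri[ok], cj[ok]):
                match_count[a][gi[r], hj[c]] += 1
    scores = np.zeros(len(alphas))
    for a in range(len(alphas)):
        fn = len(gt) - tp[a]
        fp = len(hyp) - tp[a]
        det_a = tp[a] / (tp[a] + fn + fp) if tp[a] + fn + fp > 0 else 0.0
        ass_a = 0.0
        if tp[a] > 0:
            mc = match_count[a]
            jac = mc / (gt_count[:, None] + hyp_count[None, :] - mc)
            ass_a = (mc * jac).sum() / tp[a]
        scores[a] = np.sqrt(det_a * ass_a)
    return float(scores.mean())


def main():
    gt = read_mot(sys.argv[1])
    hyp = read_mot(sys.argv[2])
    out = clear_mot(gt, hyp)
    out["IDF1"] = idf1(gt, hyp)
    out["HOTA"] = hota(gt, hyp)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
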