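"""Independent pinhole-projection oracle.

Implements the standard computer-vision point projection (the documented
OpenCV projectPoints convention: world -> camera rigid transform, perspective
division, radial k1/k2/k3 + tangential p1/p2 distortion on normalized
coordinates, intrinsic matrix to pixels) in NumPy, independent of the R
implementation under test.

Reads JSON on stdin:
  {"points": [[x,y,z],...], "R": [[...]x3], "t": [tx,ty,tz],
   "fx":..., "fy":..., "cx":..., "cy":...,
   "k1":..., "k2":..., "k3":..., "p1":..., "p2":...}
Writes JSON [[u,v],...] on stdout.
"""
import json
import sys

import numpy as np


def project(msg):
    pts = np.asarray(msg["points"], dtype=float)
    R = np.asarray(msg["R"], dtype=float)
    t = np.asarray(msg["t"], dtype=float)
    xc = pts @ R.T + t
    x = xc[:, 0] / xc[:, 2]
    y = xc[:, 1] / xc[:, 2]
    r2 = x * x + y * y
    k1, k2, k3 = msg.get("k1", 0.0), msg.get("k2", 0.0), msg.get("k3", 0.0)
    p1, p2 = msg.get("p1", 0.0), msg.get("p2", 0.0)
    radial = 1.0 + k1 * r2 + k2 * r2**2 + k3 * r2**3
    xd = x * radial + 2.0 * p1 * x * y + p2 * (r2 + 2.0 * x * x)
    yd = y * radial + p1 * (r2 + 2.0 * y * y) + 2.0 * p2 * x * y
    u = msg["fx"] * xd + msg["cx"]
    v = msg["fy"] * yd + msg["cy"]
    return np.stack([u, v], axis=1)


if __name__ == "__main__":
    msg = json.load(sys.stdin)
    out = project(msg)
    json.dump(out.tolist(), sys.stdout)
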