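"""Line-delimited JSON solver worker.

Reads one JSON request per line on a socket (or stdin in --oneshot mode),
solves each LP/MILP in the request batch with HiGHS via scipy.optimize.milp,
and writes one JSON response line. Exits when the peer closes the stream.

Request:  {"op": "solve_batch", "problems": [<problem>, ...]}
Problem:  {"nvar": int,
           "obj": [..] or null (feasibility),
           "sense": "min"|"max",
           "lb": [..], "ub": [..]   (null entries = +/-inf),
           "integrality": [0/1,..] or null,
           "A": {"i": [..], "j": [..], "x": [..]}  (1-based triplets),
           "rlb": [..], "rub": [..],
           "time_limit": seconds or null,
           "mip_gap": float or null}
Response: {"solutions": [{"status": "optimal"|"infeasible"|"unbounded"|
                          "limit"|"error", "objective": f, "x": [..]}]}
"""
import json
import socket
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

_STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded"}


def _num(v, default):
    return default if v is None else float(v)


def _aslist(v):
    if v is None:
        return []
    if isinstance(v, (int, float)):
        return [v]
    return list(v)


def solve_one(p):
    n = int(p["nvar"])
    c = np.zeros(n) if p.get("obj") is None else np.asarray(
        [_num(v, 0.0) for v in _aslist(p["obj"])], dtype=float)
    sign = -1.0 if p.get("sense") == "max" else 1.0
    lb = np.asarray([_num(v, -np.inf) for v in _aslist(p["lb"])], dtype=float)
    ub = np.asarray([_num(v, np.inf) for v in _aslist(p["ub"])], dtype=float)
    integrality = np.zeros(n)
    intg = p.get("integrality")
    if intg not in (None, [], {}):
        integrality = np.asarray(_aslist(intg), dtype=float)
    A = p.get("A") or {"i": [], "j": [], "x": []}
    rlb = [_num(v, -np.inf) for v in _aslist(p.get("rlb"))]
    rub = [_num(v, np.inf) for v in _aslist(p.get("rub"))]
    m = max(len(rlb), len(rub))
    rlb = np.asarray(rlb + [-np.inf] * (m - len(rlb)))
    rub = np.asarray(rub + [np.inf] * (m - len(rub)))
    Am = sparse.csr_matrix(
        (np.asarray(_aslist(A["x"]), dtype=float),
         (np.asarray(_aslist(A["i"]), dtype=int) - 1,
          np.asarray(_aslist(A["j"]), dtype=int) - 1)),
        shape=(m, n))
    opts = {"presolve": True}
    if p.get("time_limit") is not None:
        opts["time_limit"] = float(p["time_limit"])
    if p.get("mip_gap") is not None:
        opts["mip_rel_gap"] = float(p["mip_gap"])
    cons = [LinearConstraint(Am, rlb, rub)] if m else []
    try:
        res = milp(sign * c, constraints=cons, integrality=integrality,
                   bounds=Bounds(lb, ub), options=opts)
    except Exception as exc:  # defensive: report, keep batch going
        return {"status": "error", "message": str(exc)}
    out = {"status": _STATUS.get(res.status, "error")}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(sign * res.fun)
    return out


def handle(line):
    req = json.loads(line)
    if req.get("op") == "ping":
        return {"pong": True}
    if req.get("op") == "quit":
        return None
    sols = [solve_one(p) for p in req["problems"]]
    return {"solutions": sols}


def serve_stream(rf, wf):
    for line in rf:
        line = line.strip()
        if not line:
            continue
        resp = handle(line)
        if resp is None:
            break
        wf.write(json.dumps(resp) + "\n")
        wf.flush()


def main():
    if len(sys.argv) > 1 and sys.argv[1] == "--oneshot":
        serve_stream(sys.stdin, sys.stdout)
        return
    portfile = sys.argv[1]
    srv = socket.create_server(("127.0.0.1", 0))
    port = srv.getsockname()[1]
    with open(portfile + ".tmp", "w") as fh:
        fh.write(str(port))
    import os
    os.replace(portfile + ".tmp", portfile)
    srv.settimeout(60)
    try:
        conn, _ = srv.accept()
    except socket.timeout:
        return
    with conn, conn.makefile("r") as rf, conn.makefile("w") as wf:
        serve_stream(rf, wf)


if __name__ == "__main__":
    main()
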