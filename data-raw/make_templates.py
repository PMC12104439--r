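# Generate the bundled residue template tables from the PDB Chemical
# Component Dictionary ideal coordinates shipped with biotite.
# Output: inst/extdata/residue_atoms.tsv, inst/extdata/residue_bonds.tsv
import numpy as np
import biotite.structure.info as info

AA = ["ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
      "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"]
NT = ["A","C","G","U"]

# atoms never present in a polymerised residue
DROP = {"OXT","HXT","H2","OP3","HOP3","HOP2","HO3'"}
# leaving atoms that only exist on the free 5' terminus keep their names;
# we keep OP1/OP2/P/O5' (polymer) and drop the extra 3'-OH hydrogen

rows_a, rows_b = [], []
for res in AA + NT:
    st = info.residue(res)
    keep = ~np.isin(st.atom_name, list(DROP))
    st = st[keep]
    names = list(st.atom_name)
    if res in NT:
        # the CCD ideal ribose is flat; mirror O2' (and its H) to the other
        # sugar face so idealized A-form-like helices are clash-free
        P = {a: st.coord[names.index(a)] for a in ("C1'", "C2'", "C3'")}
        n = np.cross(P["C1'"] - P["C2'"], P["C3'"] - P["C2'"])
        n /= np.linalg.norm(n)
        for a in ("O2'", "HO2'"):
            i = names.index(a)
            v = st.coord[i] - P["C2'"]
            st.coord[i] = P["C2'"] + v - 2 * np.dot(v, n) * n
    if res in ("C", "U"):
        # rotate the pyrimidine base about the glycosidic bond so the O2
        # carbonyl clears the (mirrored) O2' in helical fixtures
        sugar = {"P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                 "O3'", "C2'", "O2'", "C1'", "H5'", "H5''", "H4'", "H3'",
                 "H2'", "HO2'", "H1'"}
        c1 = st.coord[names.index("C1'")]
        ax = st.coord[names.index("N1")] - c1
        ax = ax / np.linalg.norm(ax)
        th = np.radians(135.0)
        K = np.array([[0, -ax[2], ax[1]], [ax[2], 0, -ax[0]],
                      [-ax[1], ax[0], 0]])
        R = np.eye(3) + np.sin(th) * K + (1 - np.cos(th)) * (K @ K)
        for i, nm in enumerate(names):
            if nm in sugar:
                continue
            st.coord[i] = c1 + R @ (st.coord[i] - c1)
    for i, nm in enumerate(names):
        x, y, z = st.coord[i]
        rows_a.append((res, nm, st.element[i], f"{x:.3f}", f"{y:.3f}", f"{z:.3f}"))
    bl = st.bonds.as_array()
    for i, j, _ in bl:
        rows_b.append((res, names[i], names[j]))

with open("inst/extdata/residue_atoms.tsv", "w") as f:
    f.write("res\tatom\telement\tx\ty\tz\n")
    for r in rows_a:
        f.write("\t".join(r) + "\n")
with open("inst/extdata/residue_bonds.tsv", "w") as f:
    f.write("res\tatom1\tatom2\n")
    for r in rows_b:
        f.write("\t".join(r) + "\n")
print(len(rows_a), "atoms,", len(rows_b), "bonds")
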