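# Generate the synthetic RNA backbone suite library (46 cluster centers in the
# 7D dihedral space: delta-1, epsilon-1, zeta-1, alpha, beta, gamma, delta).
# The first center is the canonical A-form suite; the remaining centers are
# built deterministically from combinations of canonical backbone torsion
# rotamer values, mimicking the size and spread of the reference suite set.
import itertools

# the A-form anchor uses the backbone torsions of the bundled templates
# (whose idealized ribose is flat, delta ~ +98) so that the toy A-form
# builder sits exactly on this center
aform = (98, -153, -71, -68, 178, 54, 98)

deltas  = [98, 147]
epsils  = [-153, -98]
zetas   = [-71, 60, 170]
alphas  = [-65, 65, 165]
betas   = [174, 80]
gammas  = [54, -170, -65]

combos = []
for d1, e, z, a, b, g, d in itertools.product(
        deltas, epsils, zetas, alphas, betas, gammas, deltas):
    combos.append((d1, e, z, a, b, g, d))

# deterministic thinning: keep combos well separated from those already kept
def wrapdiff(x, y):
    d = abs(x - y) % 360
    return min(d, 360 - d)

def dist(u, v):
    return sum(wrapdiff(a, b) ** 2 for a, b in zip(u, v)) ** 0.5

kept = [aform]
for c in combos:
    if len(kept) == 46:
        break
    if all(dist(c, k) > 60 for k in kept):
        kept.append(c)
assert len(kept) == 46, len(kept)

names = ["1a"] + ["s%02d" % i for i in range(2, 47)]
with open("inst/extdata/rna_suites_synthetic.tsv", "w") as f:
    f.write("suite\tdelta_m1\tepsilon_m1\tzeta_m1\talpha\tbeta\tgamma\tdelta\n")
    for nm, c in zip(names, kept):
        f.write(nm + "\t" + "\t".join(str(v) for v in c) + "\n")
print("wrote", len(kept), "suite centers")
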