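---
title: "Fragmented permutationally invariant polynomial surfaces: methods"
author: "pipfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmented permutationally invariant polynomial surfaces: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipfrag)
```

## The model

A potential energy surface is represented as a linear expansion

$$V(\mathbf{x}) = \sum_{i=1}^{n_p} c_i\, p_i(\mathbf{x}),$$

where the $p_i$ are *permutationally invariant polynomials* (PIPs) in the
Morse variables $x_l = \exp(-r_l/\lambda)$, one per unordered atom pair,
with $r_l$ the interatomic distance and $\lambda$ a range parameter. A PIP
is the sum of one orbit of monomials under the group of allowed atom
permutations (identical nuclei that are declared interchangeable), so the
fitted surface is exactly invariant under those permutations by
construction. The coefficients $c_i$ come from a linear least-squares fit
to electronic energies and, when available, Cartesian gradients.

Morse variables decay exponentially with distance. For a large molecule
most atom pairs are far apart most of the time, their variables are
numerically negligible, and any basis function containing them contributes
nothing. That observation motivates *fragmentation*: cover the molecule
with (possibly overlapping) subsets of atoms, build a full PIP basis for
each fragment in its own pair variables, and fit with the union of the
fragment bases. Pairs never co-fragmented are dropped outright. Overlap is
deliberate and common — shared atoms carry the couplings — but it makes
the naive union redundant: polynomials supported entirely on shared pairs
appear in several fragment bases. This package removes those duplicates
exactly and renumbers the survivors, which is the step that makes the
fragmented basis both compact and well defined.

## Basis generation and the counting oracle

`generate_basis()` enumerates every monomial of total degree up to the
requested order in the fragment-internal pair variables, canonicalizes each
monomial under the induced action of the fragment's permutation group (the
group permutes atoms; pairs, and hence variables, follow), and keeps one
polynomial per orbit. Two deliberate conventions:

* **The constant (degree-0) term is a basis member** and is included in all
  reported counts. This is the convention under which the package
  reproduces the published basis sizes for the benchmark fragmentations
  (N-methylacetamide and glycine) exactly; the single inconsistent printed
  entry (the glycine full-molecule order-3 count) is discussed under
  *Known limitations*.
* **Ordering is grade-lexicographic**: by degree, then by the canonically
  least orbit member encoded over parent pair indices. Whether upstream
  monomial-symmetrization codes order their output the same way is
  unknowable from counts alone; only sizes and values are comparable, so
  determinism across runs was the design goal, not order compatibility.

`burnside_count()` is the independent check: it counts orbits by Burnside's
lemma — the group average of the number of monomials each element fixes,
computed in closed form from the cycle structure of the induced pair
permutation — without enumerating a single monomial. Generator and oracle
agree exactly on every spec the test suite throws at them.

Internally a degree-$k$ monomial is a sorted $k$-vector of variable
indices, encoded as a base-$(n_{\text{vars}}+1)$ integer so that numeric
order equals lexicographic order; canonicalization is a running minimum of
encoded images over group elements, fully vectorized over all monomials of
one degree. The encoding is guarded against exceeding $2^{53}$.

## Merging and duplicate elimination

`merge_bases()` concatenates fragment bases (already expressed in parent
pair indices) and deletes duplicates. The duplicate key is the **entire
canonical orbit** — the sorted set of encoded orbit monomials — not the
representative alone: fragments with different symmetry blocks can share a
representative while generating different orbits, and only identical orbits
define identical functions. The first fragment in list order keeps its
copy; exactly one constant survives; provenance and renumbering maps are
retained so fragment-local coefficients remain traceable. A property test
requires the merged key set to be independent of fragment input order,
which any correct deletion strategy must satisfy.

Merged sizes obey inclusion–exclusion: for two fragments the number of
shared polynomials equals the size of the invariant basis over the common
atoms' pairs under the common block structure. The suite verifies this
identity on random fragmentations that pass the permutational-consistency
rule (atoms declared to permute must appear together wherever any of them
appears, inside one block). `validate_fragmentation()` checks that rule but
is advisory by default — deliberately choosing less symmetry than the
molecule admits (e.g. ignoring permutations of equivalent carbons) is
legitimate — and fatal only under `--strict` in the CLI. The package also
allows permuting blocks that span chemically distinct elements; chemistry
is left to the user.

## Fitting, gradients, and numerical choices

`design_matrix()` builds one row per energy and, per gradient-carrying
record, $3N$ rows of $\sum_l (\partial p_i/\partial x_l)(\partial
x_l/\partial a_{j,k})$, scaled by the gradient weight. Choices that matter:

* **Solver**: singular value decomposition with a relative cutoff
  (default $10^{-10}$), giving the minimal-norm solution. This is what
  lets a duplicate-containing concatenated basis and its deduplicated
  counterpart yield *identical* predictions — rank deficiency is expected,
  not an error. Two steps of iterative refinement recover the last few
  digits on ill-conditioned systems; the suite checks concatenated vs
  deduplicated predictions agree below $10^{-8}$ cm$^{-1}$.
* **Gradient weight**: default 1 (no published prescription exists for the
  relative weighting); exposed as a parameter, 0 drops gradient rows.
* **$\lambda = 2$ bohr** by default, the field's customary choice;
  configurable everywhere.
* **Units**: bohr internally; the dataset reader converts from Å on
  request. Energies are opaque cm$^{-1}$ values — absolute or relative to
  any reference, the fit does not care; an optional min-shift is stored if
  requested.
* **Degenerate geometries**: coincident atoms are an error in fitting
  paths and a warning in exploratory evaluation (the Morse variable would
  hit 1 exactly; no published treatment of $r \to 0$ exists).

`evaluate_gradient()` exploits the structural sparsity of
$\partial x_l/\partial a_{j,k}$: atom $j$'s coordinates enter only the
$N-1$ variables whose pair contains $j$, so the evaluation branches per
atom and skips structural zeros. A dense unbranched path exists purely as
an oracle; the two agree to $10^{-12}$.

`build_evaluation_scheme()` compiles a basis into topologically ordered
instructions — monomials factored as (earlier monomial) × (variable) where
the sub-monomial exists, PIPs as explicit orbit sums — with a bit-for-bit
(to float tolerance) equivalence obligation against direct evaluation.
Factorization is an optimization pass only; PIP semantics are always the
orbit sum. The serialized JSON basis carries the scheme in place of
generated source code.

## Pruning and extension

Post-fit basis surgery is scored at the per-variable **maxima of the Morse
variables over the dataset**: a polynomial's value there bounds its
possible contribution on the sampled region. `prune_basis()` discards the
lowest-scoring polynomials (never the constant; ties broken by removing
the higher index first). `extend_basis()` forms pairwise products of
existing PIPs up to a target degree; each product is re-symmetrized and
split into canonical orbits *before* scoring (a product of invariants is
invariant, but its support may decompose across orbits — scoring after
splitting keeps each added term independently selectable), already-present
orbits are discarded, and the highest-scoring survivors are added.
Both operations renumber grade-lexicographically, and an invariance suite
re-checks permutational symmetry after every prune/extend. Nested
least-squares guarantees the expected RMSE monotonicity, which the tests
assert rather than any particular coefficient count: published
prune/extend trajectories depend on an undeposited dataset's Morse maxima
and are not reproducible quantities.

## Stationary-point analysis

`minimize_geometry()` runs BFGS on Cartesians with the analytic gradient
(an `fnscale` keeps the first quasi-Newton step near 0.1 bohr even with
large starting gradients — a degree-limited polynomial surface is
unbounded far from the data, so wild first steps must be prevented), then
polishes with pseudo-inverse Newton steps that project out the six
rigid-body null directions, converging to gradient infinity norms of
$10^{-8}$ cm$^{-1}$/bohr and better. `pes_hessian()` uses central finite
differences of the *analytic* gradient (step $10^{-4}$ bohr, symmetrized);
differencing gradients once is markedly less noisy than differencing
energies twice. `harmonic_frequencies()` diagonalizes
$M^{-1/2}HM^{-1/2}$ and converts eigenvalues with CODATA-2018 constants;
negative eigenvalues are reported as negative (imaginary) wavenumbers.
Linear molecules are detected by a moment-of-inertia threshold (5 rather
than 6 removed modes). No minimizer tolerance or differencing step is
published for the benchmark studies; the defaults here are stated above
and configurable.

## The synthetic generator

`make_surrogate()` provides analytic stand-in surfaces because the ab
initio datasets behind the published benchmarks were not deposited. Two
modes: a **pairwise-Morse** sum $\sum D(1-e^{-\alpha(r-r_0)})^2$ with
parameters keyed by unordered species pair (hence exactly
permutation-invariant), and a **pip-combo** mode — an exact linear
combination of a known basis, the end-to-end parameter-recovery oracle.
Pairwise parameters are drawn reproducibly from a seed within ranges
typical of covalent wells (D 5000–40000 cm$^{-1}$, $\alpha$ 0.8–1.6
bohr$^{-1}$); when a reference geometry is supplied, each pair type's
$r_0$ is anchored to its mean reference distance so the reference sits in
the surrogate's well, as a real fitting reference would.

`sample_dataset()` emulates the published datasets' structure — energies
confined below a ceiling (10000 cm$^{-1}$ by default) above the minimum,
most configurations near the minimum, analytic gradients on every record —
by accept–reject Gaussian displacement sampling. It does **not** emulate
molecular-dynamics correlation, anharmonic sampling bias, DFT energetics,
or multi-well topology; passing tests therefore demonstrate correctness of
the basis algebra, the fit, and the derivatives, not chemical accuracy on
real molecules. Published RMSE/RMSG/timing values depend on the
undeposited data and hardware and are deliberately not targets.

The shipped toy systems (`a3bc`, 5 atoms; `a2b2cd`, 6 atoms) are small
enough that every oracle — exhaustive orbit enumeration, finite
differences, inclusion–exclusion — runs in seconds. The test suite uses
datasets of 50–150 records, polynomial orders 1–4, and random symmetry
specs up to 7 atoms and degree 4 (capping the enumeration work per spec at
about $3\times10^7$ monomial-element operations, which keeps full
symmetric groups exercised at degree ≤ 3); these sizes were chosen as
desk-scale while still covering every code path, including the 46654-term
glycine-sized full basis.

## Known limitations

* The glycine full-molecule order-3 basis size is printed as 4683 in the
  benchmark literature, while the constant-included convention that
  reproduces *every other* published count (8040, 6056, 5240, 816, 1806,
  1022, 1704, 46654, 5348, 9337) yields 4684 here, by both the generator
  and the Burnside oracle. The package treats that single entry as a
  printing inconsistency and does not assert it.
* The published five-fragment scheme for the 12-atom benchmark is stated
  with ambiguous atom indices; its counts are reproducible only given an
  explicit assignment, which the user must supply.
* Fragment discovery is out of scope: fragmentation is user input, and
  choosing it well remains an art.
* Degree-limited polynomial surfaces are unreliable outside the sampled
  region; the minimizer guards against runaway steps but extrapolation is
  inherently unsafe.
* No anharmonic (VPT2/VSCF) analysis and no transition-state search are
  provided.
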