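# pipfrag

Fragmented permutationally invariant polynomial (PIP) potential energy
surfaces in R.

## The problem

High-dimensional molecular potential energy surfaces are widely fitted as a
linear expansion

    V(x) = Σᵢ cᵢ pᵢ(x),        xₗ = exp(−rₗ/λ),

where the `pᵢ` are permutationally invariant polynomials in Morse variables
`xₗ` of the interatomic distances `rₗ` (λ ≈ 2 bohr), each `pᵢ` being the
orbit sum of a monomial under the group of allowed permutations of
identical atoms. The basis size explodes with atom count, which
historically capped full-molecule PIP fits near ten atoms. Because Morse
variables vanish exponentially with distance, a larger molecule can instead
be covered by *overlapping fragments*, each with a tractable PIP basis;
the union of fragment bases then fits the whole molecule — provided the
duplicated polynomials that overlapping fragments generate are eliminated
exactly, and provided the fragment symmetries are chosen consistently so
the merged surface stays permutationally invariant.

`pipfrag` implements that workflow for people building PESs from electronic
energies and gradients:

* PIP basis generation by monomial symmetrization (`generate_basis()`),
  with an independent closed-form Burnside orbit-counting oracle
  (`burnside_count()`),
* fragmentation machinery: consistency validation, variable union, merging
  with exact orbit-key duplicate deletion (`merge_bases()`),
* joint energy + gradient linear least squares with a rank-tolerant SVD
  solver (`pip_fit()`), analytic gradients with per-atom sparsity
  branching (`evaluate_gradient()`),
* basis pruning/extension scored at the dataset's Morse-variable maxima
  (`prune_basis()`, `extend_basis()`),
* geometry minimization and harmonic frequencies on the fitted surface
  (`harmonic_analysis()`),
* a synthetic surrogate-PES module (`make_surrogate()`,
  `sample_dataset()`) and dataset/basis/coefficient file formats, plus a
  `pipfrag` command-line wrapper (`exec/pipfrag`).

## Worked example 1: a fragmented basis for a 12-atom molecule

Two overlapping 9-atom fragments of a 12-atom molecule (two methyl groups
whose three H atoms permute; atoms 4–9 shared):

```r
library(pipfrag)

frags <- list(
  fragment_spec(c(1, 2, 3, 4, 5, 6, 7, 8, 9),    c(3, 1, 1, 1, 1, 1, 1)),
  fragment_spec(c(10, 11, 12, 4, 5, 6, 7, 8, 9), c(3, 1, 1, 1, 1, 1, 1)))

parent <- fragment_spec(c(1, 2, 3, 10, 11, 12), c(3, 3))  # the two H triples
validate_fragmentation(parent, frags)
#> fragmentation check: PASS

bases  <- lapply(frags, generate_basis, max_degree = 3, n_atoms = 12)
merged <- merge_bases(bases)
merged
#> <pip_basis> 5240 polynomials (degree <= 3), 57 of 66 Morse variables retained, 2 fragment(s)
#>   merged basis: 816 duplicated polynomial(s) removed
#>   per degree: 0:1  1:29  2:442  3:4768

burnside_count(frags[[1]], 3)   # oracle for each 3028-term fragment basis
#> [1] 3028
```

Reading: of the 66 pair variables of a 12-atom molecule, 57 survive (the 9
cross-methyl pairs are dropped); the two 3028-term fragment bases overlap
in 816 polynomials supported on the shared atoms, leaving 5240 unique
basis functions.

## Worked example 2: fit and harmonic analysis on a synthetic surface

```r
sys <- toy_system("a3bc")                       # 5-atom methyl-like toy
pes <- make_surrogate(sys$species, "pairwise", seed = 1,
                      reference = sys$geometry)
ds  <- sample_dataset(pes, sys$geometry, n = 150, sigma = 0.06,
                      cutoff = 10000, seed = 1) # energies + gradients
fit <- pip_fit(ds, generate_basis(sys$blocks, 3))
summary(fit)
#> Permutationally invariant polynomial fit
#>   basis: 75 PIPs, degree <= 3, 10/10 Morse variables, 1 fragment(s)
#>   data: 150 energies, 2250 gradient components (weight 1)
#>   solver: SVD, relative cutoff 1e-10, rank 75/75
#>   training RMSE = 12.847904 cm^-1
#>   training RMSG = 130.97603 cm^-1/bohr

harmonic_analysis(fit, sys$geometry, sys$masses)
#> <harmonic_result> minimum at E = -30.264697 cm^-1 (nonlinear)
#>   9 vibrational wavenumbers [cm^-1]:
#>   1499.1 1499.1 1507.9 2817.7 2817.7 2896.8 4605.3 4605.3 5246.6
#>   near-zero modes: -0.20 -0.11 -0.11  0.00  0.00  0.00
```

The RMSE/RMSG are training errors of the degree-3 fit against the
surrogate's energies (cm⁻¹) and gradient components (cm⁻¹/bohr); the
doubly degenerate wavenumber pairs reflect the C₃ᵥ symmetry of the toy
minimum, and the six near-zero modes are the rigid translations and
rotations.

See `vignette("fragmented-pip-surfaces")` for the methods account:
conventions (constant term included in all counts, grade-lexicographic
numbering, orbit-key duplicate detection), numerical choices, and known
limitations.

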