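# lorefine

Local optimization (LO) refinement for cryo-EM single particle analysis of
complexes built from rigid modules whose relative positions and orientations
fluctuate. A conventional refinement assigns each particle one consensus
orientation; for a flexible complex that consensus blurs every module.
`lorefine` re-optimizes, per particle and per module, the five projection
parameters (φ, θ, ψ, x, y) in a small neighbourhood of the consensus,
scoring candidates by the masked cross-correlation coefficient

    ρ₁₂ = Σⱼ (f₁ - ⟨f₁⟩)(f₂ - ⟨f₂⟩) / [Σⱼ (f₁ - ⟨f₁⟩)² Σⱼ (f₂ - ⟨f₂⟩)²]^½

between the experimental image f₁ and a composite simulated projection f₂ in
which only the target module moves (the remainder stays at the consensus
parameters), with the CCC evaluated only inside a 2D mask that follows the
target module. The refined parameters feed a module-wise weighted
back-projection reconstruction assessed by Fourier shell correlation against
a reference map, with resolution read at FSC = 0.5.

The search cone is spanned by a quasi-uniform direction set intersected with
a cone of semi-angle α₀ around the preliminary direction; in-plane rotation
grids are re-centred per candidate direction by parallel transport of ψ along
the connecting great circle; shifts are searched on a grid centred on the
preliminary translation. Two strategies are provided: exhaustive simultaneous
search of angles and shifts, and the cheaper separate search (random trial
angles for the shift stage, per-trial peaks averaged to a sub-pixel shift,
then an exhaustive angle sweep at that shift).

The package is aimed at method developers and students of SPA refinement:
everything runs on synthetic data generated by the built-in two-module
benchmark (continuous rigid perturbations: rotation angle ~ N(0°, 1.67°)
about a random axis through each module's centre, shifts ~ N(0 px, 1 px) per
axis; Gaussian noise at variance-ratio SNR 0.25/0.11/0.06 or a simple
analytic CTF across defocus groups). MRC2014 I/O and plain-text parameter
tables connect it to external data.

## Worked example

```r
library(lorefine)

phantom <- two_module_phantom()          # 64^3 voxels, 4 A/voxel, 2:1 mass
stack <- generate_dataset(300, phantom,
                          degradation = list(type = "gaussian", snr = 0.25),
                          seed = 1)

conv <- conventional_global_refine(stack, phantom$volume)
stack$params[, c("phi", "theta", "psi", "x", "y")] <-
  conv[, c("phi", "theta", "psi", "x", "y")]

fit <- lo_refine(stack, phantom$volume, phantom$masks[[2]],
                 refinement_config(strategy = "separate",
                                   mask = list(diameter = 24), seed = 1))
fit
#> LO-refinement (separate strategy): 300 particles, 0 failed
#>   grid evaluations: 406443; median best CCC: 0.5637
#>   median direction change: 9.38 deg; median shift change: 0.50 px
```

A full before/after comparison on one synthetic dataset:

```r
bench <- benchmark_improvement(seed = 1, n_particles = 80)
unlist(bench$resolutions)
#>    target_before     target_after nontarget_before  nontarget_after
#>         21.11620         18.17013         19.76987         32.35736
```

Resolutions are in Angstrom at FSC = 0.5 against the ground-truth phantom:
one LO pass on the small module sharpens it (21.1 → 18.2 Å here) while the
non-target module, whose misalignment is anti-correlated with the target's,
gets worse — the characteristic trade-off of module-wise refinement. Refining
each module in turn (`refine_all_modules()`) recovers both.

A thin command-line front end (`inst/scripts/lorefine`) exposes `simulate`,
`refine-global`, `lo-refine`, `reconstruct` and `fsc` subcommands over the
same functions.

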