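# probekit

Quantitative characterization of chemical probes for SAM-dependent
methyltransferases, in R.

When a small-molecule inhibitor of a methyltransferase such as PRDM9 is
discovered, a standard battery of quantitative analyses establishes what it
is and how it works: where it binds relative to the cofactor
S-adenosylmethionine (SAM), whether it competes with the peptide substrate or
depends on the cofactor, how tightly and how fast it binds, whether it
stabilizes the target in vitro and in cells, and whether it silences the
enzyme's activity on chromatin. `probekit` implements that battery as a set
of tested, reusable R functions, each exercisable on seeded synthetic data
with known ground truth — no downloads required.

It is aimed at structural bioinformaticians and assay scientists who want
scriptable, reproducible versions of analyses usually done interactively in
molecular-graphics or instrument software.

## What it computes

**Cofactor–inhibitor interface survey.** Structures are read from PDB or
mmCIF text, hydrogens are modeled geometrically, and for every
(SAM/SAH, candidate-ligand) pair the bidirectional interface tally is taken:
the number of ligand atoms strictly within 4 Å of any cofactor atom, and
vice versa. Ligands without rings, ions, waters and buffer components are
filtered out, and repeated ligand–cofactor pairs are deduplicated to the
instance with the largest combined tally. This is the measure by which an
inhibitor that wraps around the bound cofactor stands out from inhibitors
that merely touch its labile methyl group.

**Superposition and steric clash.** Rigid-body least-squares (Kabsch)
superposition over paired Cα atoms, with optional iterative outlier
rejection, reporting RMSD; steric clashes are flagged where an interatomic
distance falls below the Bondi van der Waals sum minus 0.4 Å.

**Dose–response and mechanism of action.** Four-parameter logistic fits

&nbsp;&nbsp;&nbsp;&nbsp;*y* = bottom + (top − bottom) / (1 + (*x*/IC50)^hill)

give IC50; the dependence of IC50 on substrate concentration [S] decides the
mechanism. For a substrate-competitive inhibitor IC50([S]) = K_i (1 + [S]/K_m),
so the intercept of the IC50-versus-[S] line is K_i; a falling IC50 with
rising co-substrate indicates an uncompetitive, cofactor-dependent mode.

**Thermal shift.** Boltzmann sigmoid fits of melt curves,
*F*(T) = F_pre + (F_post − F_pre)/(1 + exp((T_m − T)/a)), give T_m;
ΔT_m = T_m(+ligand) − T_m(apo) above a 2 °C threshold calls binding.

**SPR kinetics.** Global 1:1 Langmuir fits across analyte concentrations,
dR/dt = k_on·C·(R_max − R) − k_off·R, share k_on, k_off and R_max and give
K_d = k_off/k_on; steady-state fits of R_eq = R_max·C/(K_d + C) provide the
equilibrium cross-check.

**ChIP-qPCR enrichment.** Enrichment 2^−ΔCq with the exponential-scale error
limits |2^−(ΔCq±s) − 2^−ΔCq|, s = √(SD_input² + SD_target²), H3
normalization with quadrature propagation in Cq space, and the left-tailed
two-sample t-test (pooled or Welch) for treatment effects.

## Worked example

```r
library(probekit)

# dose-response: 10-point titration, triplicate, 5% CV noise
dr  <- simulate_dose_response(synth_spec(1, "dose_response", cv = 0.05))
fit_4pl(dr$data$concentration, dr$data$response)
#> <4PL fit> IC50 = 6.74e-08 M, hill = 0.91, range [-0.434, 105]

# mechanism of action from an IC50-versus-substrate series
ser <- simulate_ic50_series(synth_spec(2, "ic50_series"))
classify_moa(ser$data$concentration, ser$data$ic50, se = ser$data$se)
#> <MOA> competitive (substrate axis), slope 0.0162 (p = 1.31e-84), Ki = 6.41e-08 M +/- 3.9e-09

# cellular thermal shift
apo  <- simulate_melt_curve(synth_spec(3, "melt_curve", tm = 52))$data
holo <- simulate_melt_curve(synth_spec(4, "melt_curve", tm = 54))$data
thermal_shift(apo, holo, mode = ">=")
#> <thermal shift> Tm 52.0 -> 54.0 C, dTm = +2.01 C: binding

# SPR kinetics
spr <- simulate_spr_traces(synth_spec(5, "spr_traces"))
fit_spr_kinetic(spr$data)
#> <SPR 1:1 fit> kon = 1.2e+06 /M/s, koff = 0.1 /s, Kd = 8.32e-08 M, Rmax = 30.0 RU

# ChIP-qPCR enrichment with error limits
enrichment_with_limits(27, 25, sd_target = 0.4, sd_input = 0.3)
#> <enrichment> 2^-dCq = 0.25 (+0.104/-0.0732), dCq = 2.000, s = 0.500

# interface tally on a generated cofactor-ligand complex
toy <- make_toy_complex(synth_spec(6, "toy_complex",
                                   n_cofactor = 3L, distances = c(3.2, 3.8)))
s     <- parse_structure(text = toy$pdb_text, entry_id = "toy")
comps <- classify_components(s)
roles <- vapply(comps, `[[`, "", "role")
tally_interface(comps[[which(roles == "cofactor_SAM")]],
                comps[[which(roles == "candidate_ligand")]])
#> <interface_tally> SAM~LIG @ <4 A: 3 cofactor / 2 ligand atoms
```

The fitted IC50 (67 nM here) scatters around the generating 80 nM with the
simulated 5% multiplicative assay noise; the MOA call recovers the
generating K_i of 65 nM within its standard error; the SPR fit returns the
generating k_on = 1.2×10⁶ M⁻¹s⁻¹ and k_off = 0.1 s⁻¹, i.e. K_d = 83 nM; and
the tally reproduces the engineered ground truth of the toy complex exactly.

A thin command-line wrapper over the same stages ships at
`inst/cli/probekit.R` (`survey`, `superpose`, `moa`, `thermal`, `spr`,
`chip`, `synth` subcommands); every run writes a JSON manifest with its
parameters, input digests and seed.

## Vignette

`vignettes/probekit-methods.Rmd` documents the models, their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generators do and do not emulate, and the package's numerical conventions.
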