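# Seeded synthetic-data generators.
#
# Every input class the analysis modules consume can be generated with known
# ground truth: toy cofactor-ligand complexes with engineered interface
# tallies, 4PL dose-response tables, IC50-vs-concentration series under
# competitive/uncompetitive closed forms, Boltzmann melt curves, 1:1 Langmuir
# SPR traces, and qPCR Cq tables. The same spec always produces identical
# output (a local RNG stream is used and restored).

# Idealized SAM geometry (computed small-molecule conformer, CCD atom names).
# Adenine + ribose rings make ring perception on the cofactor testable
# offline; coordinates are an energy-minimized conformer, not deposited data.
.SAM_TEMPLATE <- data.frame(
  atom_name = c("CE", "SD", "CG", "CB", "CA", "N", "C", "O", "OXT",
                "C5'", "C4'", "O4'", "C1'", "N9", "C8", "N7", "C5", "C6",
                "N6", "N1", "C2", "N3", "C4", "C2'", "O2'", "C3'", "O3'"),
  element = c("C", "S", "C", "C", "C", "N", "C", "O", "O",
              "C", "C", "O", "C", "N", "C", "N", "C", "C",
              "N", "N", "C", "N", "C", "C", "O", "C", "O"),
  x = c(-3.353, -2.828, -2.920, -4.356, -4.750, -4.837, -3.805, -3.301,
        -3.665, -1.033, -0.277, 0.063, 1.339, 2.247, 1.994, 3.066, 4.032,
        5.372, 5.996, 6.097, 5.484, 4.215, 3.545, 1.832, 1.446, 1.065, 0.953),
  y = c(1.344, 1.718, 0.027, -0.384, -0.197, 1.246, -0.963, -2.042, -0.389,
        1.856, 0.645, -0.270, -0.880, -0.654, 0.009, 0.084, -0.628, -0.929,
        -0.520, -1.625, -2.026, -1.797, -1.093, -0.262, -1.066, 1.047, 1.543),
  z = c(2.311, 0.629, -0.050, -0.402, -1.872, -2.263, -2.883, -2.459, -4.007,
        0.905, 1.452, 0.396, 0.696, -0.416, -1.588, -2.353, -1.678, -1.978,
        -3.149, -1.072, 0.063, 0.461, -0.468, 2.014, 3.148, 2.061, 3.391),
  stringsAsFactors = FALSE
)

#' Idealized SAM template coordinates
#'
#' @return data.frame of 27 heavy atoms (`atom_name`, `element`, `x`, `y`,
#'   `z`) of an idealized S-adenosylmethionine conformer.
#' @export
sam_template <- function() .SAM_TEMPLATE

# evaluate expr with a private, seeded RNG stream; global stream untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a synthetic-data specification
#'
#' @param seed integer RNG seed; the same spec always yields identical output.
#' @param scenario one of `"toy_complex"`, `"dose_response"`, `"ic50_series"`,
#'   `"melt_curve"`, `"spr_traces"`, `"cq_table"`.
#' @param ... scenario parameters overriding the defaults (see the generator
#'   documentation for each scenario).
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed, scenario = c("toy_complex", "dose_response",
                                          "ic50_series", "melt_curve",
                                          "spr_traces", "cq_table"), ...) {
  scenario <- match.arg(scenario)
  structure(list(seed = as.integer(seed), scenario = scenario,
                 params = list(...)), class = "synth_spec")
}

.spec_params <- function(spec, defaults) {
  p <- utils::modifyList(defaults, spec$params)
  p
}

.lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Generate a toy cofactor-ligand complex with an engineered interface tally
#'
#' Emits PDB text containing the idealized SAM component plus a synthetic
#' ringed ligand (`LIG`) whose placement realizes a requested ground-truth
#' interface tally: `distances` gives the distance of each ligand contact
#' atom from a SAM anchor atom; atoms at or beyond `cutoff` are placed so they
#' are at least `cutoff` from every SAM atom. A deterministic seeded search
#' over anchor atoms and outward ray directions finds a placement whose
#' brute-force tally equals the request exactly; an infeasible request errors.
#'
#' Parameters (via [synth_spec()]): `n_cofactor` (ground-truth cofactor atoms
#' in contact; default 3), `distances` (ligand-atom distances from the anchor,
#' default `c(3.2, 3.8)`), `cutoff` (default 4).
#'
#' @param spec a `synth_spec` with scenario `"toy_complex"`.
#' @return list: `pdb_text` (character vector of PDB lines), `truth` (list
#'   with `n_cofactor_atoms`, `n_ligand_atoms`, `cutoff`).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "toy_complex")
  p <- .spec_params(spec, list(n_cofactor = 3L, distances = c(3.2, 3.8),
                               cutoff = 4.0, n_ray_trials = 300L))
  sam <- .SAM_TEMPLATE
  S <- as.matrix(sam[, c("x", "y", "z")])
  centroid <- colMeans(S)
  want_lig <- sum(p$distances < p$cutoff)
  want_cof <- as.integer(p$n_cofactor)
  if (want_lig == 0L) want_cof <- 0L
  anchors <- order(-sqrt(rowSums(sweep(S, 2, centroid)^2)))
  sol <- .with_seed(spec$seed, {
    found <- NULL
    for (ai in anchors) {
      anchor <- S[ai, ]
      base_ray <- .unit(anchor - centroid)
      rays <- c(list(base_ray), lapply(seq_len(p$n_ray_trials), function(i) {
        v <- stats::rnorm(3)
        u <- .unit(v)
        if (sum(u * base_ray) < 0.2) u <- .unit(u + base_ray)  # outward bias
        u
      }))
      for (ray in rays) {
        contact <- t(vapply(p$distances, function(d) anchor + d * ray, numeric(3)))
        ring_center <- anchor + ray * (max(p$distances, 0) + 9)
        n <- .perp(ray)
        m <- pracma_cross(ray, n)
        hex <- t(vapply(0:5, function(k) {
          th <- k * pi / 3
          ring_center + 1.40 * (cos(th) * n + sin(th) * m)
        }, numeric(3)))
        L <- rbind(contact, hex)
        d2 <- outer(rowSums(S^2), rowSums(L^2), `+`) - 2 * tcrossprod(S, L)
        dmat <- sqrt(pmax(d2, 0))
        got_lig <- sum(apply(dmat, 2L, min) < p$cutoff)
        got_cof <- sum(apply(dmat, 1L, min) < p$cutoff)
        # atoms requested at >= cutoff must clear every SAM atom
        far_ok <- length(p$distances) == 0L ||
          all(apply(dmat[, seq_along(p$distances), drop = FALSE], 2L, min)[
            p$distances >= p$cutoff] >= p$cutoff)
        if (got_lig == want_lig && got_cof == want_cof && far_ok) {
          found <- L
          break
        }
      }
      if (!is.null(found)) break
    }
    found
  })
  if (is.null(sol)) {
    stop("geometrically infeasible request: could not realize tally (",
         want_cof, ", ", want_lig, ") with the stated distances")
  }
  nlig <- nrow(sol)
  at <- data.frame(
    serial = seq_len(27L + nlig),
    atom_name = c(sam$atom_name, sprintf("C%02d", seq_len(nlig))),
    element = c(sam$element, rep("C", nlig)),
    alt_loc = "",
    comp_id = c(rep("SAM", 27L), rep("LIG", nlig)),
    chain_id = "A",
    seq_id = c(rep(401L, 27L), rep(402L, nlig)),
    insert = "",
    x = c(S[, 1], sol[, 1]), y = c(S[, 2], sol[, 2]), z = c(S[, 3], sol[, 3]),
    occupancy = 1, is_hetero = TRUE,
    is_hydrogen = FALSE, stringsAsFactors = FALSE
  )
  s <- .new_macromol(sprintf("toy_%d", spec$seed), at)
  list(pdb_text = write_pdb(s),
       truth = list(n_cofactor_atoms = want_cof, n_ligand_atoms = want_lig,
                    cutoff = p$cutoff))
}

#' Simulate a 4PL dose-response table
#'
#' Defaults mirror the biochemical inhibition assay: titration by 3-fold
#' dilution from 50 uM down to ~2.5 nM (10 concentrations), triplicate wells,
#' truth `bottom = 0`, `top = 100` (percent activity), `ic50 = 80e-9` M,
#' `hill = 1`, multiplicative log-normal noise with `cv = 0.05`.
#'
#' @param spec a `synth_spec` with scenario `"dose_response"`.
#' @return list: `data` (data.frame `concentration`, `replicate`, `response`),
#'   `truth` (the generating parameters).
#' @export
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "dose_response")
  p <- .spec_params(spec, list(
    concentrations = 50e-6 * 3^-(9:0), replicates = 3L,
    bottom = 0, top = 100, ic50 = 80e-9, hill = 1, cv = 0.05))
  grid <- expand.grid(concentration = p$concentrations,
                      replicate = seq_len(p$replicates))
  mu <- p$bottom + (p$top - p$bottom) / (1 + (grid$concentration / p$ic50)^p$hill)
  resp <- .with_seed(spec$seed, mu * .lognorm_noise(nrow(grid), p$cv))
  list(data = data.frame(concentration = grid$concentration,
                         replicate = grid$replicate, response = resp),
       truth = p[c("bottom", "top", "ic50", "hill", "cv")])
}

#' Simulate an IC50-versus-concentration series
#'
#' Competitive axis (`varied_axis = "substrate"`): peptide varied over the
#' assay's titration points 1.25-20 uM at saturating cofactor;
#' `IC50([S]) = ki (1 + [S]/km_substrate)` with `ki = 65e-9` M and
#' `km_substrate = 4e-6` M. Uncompetitive axis (`"cofactor"`): SAM varied
#' 22-350 uM; `IC50([C]) = k_lim (1 + km_cofactor/[C])` with
#' `km_cofactor = 70e-6` M. IC50s get multiplicative log-normal noise
#' (`cv = 0.05`) and reported standard errors `se = cv * IC50`.
#'
#' @param spec a `synth_spec` with scenario `"ic50_series"`.
#' @return list: `data` (data.frame `concentration`, `ic50`, `se`), `truth`.
#' @export
simulate_ic50_series <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "ic50_series")
  p <- .spec_params(spec, list(
    varied_axis = "substrate",
    concentrations = NULL, ki = 65e-9, km_substrate = 4e-6,
    k_lim = 66.7e-9, km_cofactor = 70e-6, cv = 0.05))
  if (is.null(p$concentrations)) {
    p$concentrations <- if (p$varied_axis == "substrate")
      c(1.25, 2.5, 5, 10, 20) * 1e-6 else c(22, 45, 90, 180, 350) * 1e-6
  }
  true_ic50 <- if (p$varied_axis == "substrate") {
    predict_ic50_competitive(p$ki, p$concentrations, p$km_substrate)
  } else {
    predict_ic50_uncompetitive(p$k_lim, p$concentrations, p$km_cofactor)
  }
  noisy <- .with_seed(spec$seed,
                      true_ic50 * .lognorm_noise(length(true_ic50), p$cv))
  se <- if (p$cv > 0) p$cv * noisy else pmax(noisy * 1e-6, 1e-15)
  list(data = data.frame(concentration = p$concentrations, ic50 = noisy, se = se),
       truth = p)
}

#' Simulate a Boltzmann melt curve
#'
#' Defaults: scan 30-70 C in 0.5 C steps, baselines 10 (folded) and 100
#' (unfolded), `tm = 52` C, transition slope `a = 1.0` C, multiplicative
#' signal noise `cv = 0.02`.
#'
#' @param spec a `synth_spec` with scenario `"melt_curve"`.
#' @return list: `data` (data.frame `temperature`, `signal`), `truth`.
#' @export
simulate_melt_curve <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "melt_curve")
  p <- .spec_params(spec, list(temperatures = seq(30, 70, by = 0.5),
                               f_pre = 10, f_post = 100, tm = 52, a = 1.0,
                               cv = 0.02))
  mu <- p$f_pre + (p$f_post - p$f_pre) / (1 + exp((p$tm - p$temperatures) / p$a))
  sig <- .with_seed(spec$seed, mu * .lognorm_noise(length(mu), p$cv))
  list(data = data.frame(temperature = p$temperatures, signal = sig),
       truth = p[c("f_pre", "f_post", "tm", "a", "cv")])
}

#' Simulate 1:1 Langmuir SPR traces
#'
#' Defaults follow the binding experiment: five analyte concentrations from
#' 1 uM by 0.33x dilution, 60 s association, 120 s dissociation sampled at
#' 0.5 s, `kon = 1.2e6` 1/M/s, `koff = 0.1` 1/s, `rmax = 30` RU, additive
#' Gaussian noise `noise_sd = 0.1` RU.
#'
#' @param spec a `synth_spec` with scenario `"spr_traces"`.
#' @return list: `data` (data.frame `time`, `response`, `concentration`),
#'   `truth`.
#' @export
simulate_spr_traces <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "spr_traces")
  p <- .spec_params(spec, list(concentrations = 1e-6 * 0.33^(0:4),
                               t_on = 60, t_off = 120, dt = 0.5,
                               kon = 1.2e6, koff = 0.1, rmax = 30,
                               noise_sd = 0.1))
  tgrid <- seq(p$dt, p$t_on + p$t_off, by = p$dt)
  rows <- lapply(p$concentrations, function(cc) {
    data.frame(time = tgrid,
               response = .langmuir_trace(tgrid, cc, p$kon, p$koff, p$rmax, p$t_on),
               concentration = cc)
  })
  df <- do.call(rbind, rows)
  if (p$noise_sd > 0) {
    df$response <- df$response +
      .with_seed(spec$seed, stats::rnorm(nrow(df), 0, p$noise_sd))
  }
  list(data = df, truth = p[c("kon", "koff", "rmax", "t_on", "t_off", "noise_sd")])
}

#' Simulate a ChIP-qPCR Cq table
#'
#' Long-format table (`locus`, `antibody`, `fraction` target/input,
#' `condition`, `replicate`, `cq`) with additive Gaussian Cq noise of stated
#' per-well standard deviation. Truth carries the per-track mean Cq values, so
#' expected enrichments and limits can be computed without re-running the
#' generator.
#'
#' Defaults: one PRDM9-dependent locus with mark enrichment falling across
#' conditions (DMSO then increasing inhibitor), H3 track constant,
#' `n_replicates = 3`, `cq_sd = 0.15`.
#'
#' @param spec a `synth_spec` with scenario `"cq_table"`.
#' @return list: `data`, `truth`.
#' @export
simulate_cq_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$scenario == "cq_table")
  p <- .spec_params(spec, list(
    locus = "intergenic_peak_1",
    conditions = c("DMSO", "MRK740_1uM", "MRK740_5uM"),
    dcq_mark = c(2.0, 3.0, 4.0),   # mark enrichment falls with inhibitor
    dcq_h3 = c(1.0, 1.0, 1.0),
    cq_input = 25, n_replicates = 3L, cq_sd = 0.15))
  rows <- list()
  truth <- list()
  .with_seed(spec$seed, {
    for (i in seq_along(p$conditions)) {
      cond <- p$conditions[i]
      for (tr in c("H3K4me3", "H3")) {
        dcq <- if (tr == "H3K4me3") p$dcq_mark[i] else p$dcq_h3[i]
        mu_t <- p$cq_input + dcq
        for (fr in c("target", "input")) {
          mu <- if (fr == "target") mu_t else p$cq_input
          rows[[length(rows) + 1L]] <- data.frame(
            locus = p$locus, antibody = tr, fraction = fr, condition = cond,
            replicate = seq_len(p$n_replicates),
            cq = stats::rnorm(p$n_replicates, mu, p$cq_sd),
            stringsAsFactors = FALSE)
        }
        truth[[paste(cond, tr, sep = ":")]] <-
          list(dcq = dcq, cq_input = p$cq_input, cq_sd = p$cq_sd)
      }
    }
  })
  list(data = do.call(rbind, rows), truth = truth)
}
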