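#' Specification for synthetic contact maps
#'
#' Desk-scale stand-ins for normalized Hi-C maps, carrying the statistical
#' structure the analysis layer assumes: power-law distance decay,
#' block-enhanced TADs along the diagonal, a plaid same-compartment
#' enrichment, and (in mitotic mode) a uniform near-diagonal band with
#' sharp decay beyond it. Ground-truth TAD boundaries and compartment
#' labels are returned alongside every map.
#'
#' @param n_loci Number of loci (default 60, i.e. 6 Mb at 100 kb).
#' @param resolution_kb Bin size (default 100).
#' @param decay_exponent Power-law slope of contact decay (default 1).
#' @param tad_blocks List of `c(start, end)` locus ranges (1-based,
#'   non-overlapping); default three equal blocks.
#' @param tad_enrichment Within-block multiplicative enrichment (default 3).
#' @param compartment_labels Character vector ("A"/"B") per locus; default
#'   alternating 1 Mb stretches.
#' @param plaid_strength Same-label enrichment factor (default 1.6);
#'   opposite-label pairs are depleted by its inverse.
#' @param plaid_min_separation Minimum locus separation at which the plaid
#'   factor applies (default 12, i.e. 1.2 Mb at 100 kb): compartmental
#'   segregation is long-range structure and must not carve short-range
#'   insulation dips.
#' @param band_width Mitotic band half-width in loci (default 6).
#' @param band_level Contact level inside the mitotic band (default 0.9).
#' @param noise_sd Lognormal multiplicative noise sd (default 0.02).
#' @param seed RNG seed for the noise (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_loci = 60, resolution_kb = 100,
                           decay_exponent = 1, tad_blocks = NULL,
                           tad_enrichment = 3, compartment_labels = NULL,
                           plaid_strength = 1.6, plaid_min_separation = 12,
                           band_width = 6,
                           band_level = 0.9, noise_sd = 0.02, seed = 1) {
  if (is.null(tad_blocks)) {
    b <- floor(n_loci / 3)
    tad_blocks <- list(c(1, b), c(b + 1, 2 * b), c(2 * b + 1, n_loci))
  }
  starts <- vapply(tad_blocks, `[`, numeric(1), 1)
  ends <- vapply(tad_blocks, `[`, numeric(1), 2)
  stopifnot(all(starts >= 1), all(ends <= n_loci), all(starts <= ends),
            all(starts[-1] > ends[-length(ends)]),
            tad_enrichment > 0, plaid_strength > 0, band_width >= 1,
            decay_exponent > 0, band_level > 0, band_level <= 1)
  if (is.null(compartment_labels)) {
    # 1 Mb stretches in a mixed-parity arrangement: a strictly alternating
    # pattern would be invisible to observed/expected at the coarse scale
    # (every coarse diagonal would be label-homogeneous)
    stretch <- max(1, round(1000 / resolution_kb))
    pattern <- c("A", "A", "B", "A", "B", "B")
    compartment_labels <- rep(rep(pattern,
                                  length.out = ceiling(n_loci / stretch)),
                              each = stretch)[seq_len(n_loci)]
  }
  stopifnot(length(compartment_labels) == n_loci)
  structure(list(n_loci = as.integer(n_loci), resolution_kb = resolution_kb,
                 decay_exponent = decay_exponent, tad_blocks = tad_blocks,
                 tad_enrichment = tad_enrichment,
                 compartment_labels = compartment_labels,
                 plaid_strength = plaid_strength,
                 plaid_min_separation = as.integer(plaid_min_separation),
                 band_width = as.integer(band_width),
                 band_level = band_level,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_spec")
}

spec_region <- function(spec) {
  genomic_region("chrS", 0, (spec$n_loci - 1) * spec$resolution_kb / 1000,
                 spec$resolution_kb)
}

# multiplicative factor matrices for the planted features
tad_factor_matrix <- function(spec, strength = spec$tad_enrichment) {
  n <- spec$n_loci
  f <- matrix(1, n, n)
  for (b in spec$tad_blocks) {
    idx <- b[1]:b[2]
    f[idx, idx] <- strength
  }
  f
}

# compartment plaid is long-range structure: pairs closer than the
# separation floor keep factor 1 so TAD insulation stays plaid-free
plaid_factor_matrix <- function(spec, strength = spec$plaid_strength) {
  same <- outer(spec$compartment_labels, spec$compartment_labels, "==")
  f <- ifelse(same, strength, 1 / strength)
  d <- abs(row(f) - col(f))
  f[d < spec$plaid_min_separation] <- 1
  f
}

noise_matrix <- function(spec) {
  n <- spec$n_loci
  if (spec$noise_sd <= 0) return(matrix(1, n, n))
  set.seed(spec$seed)
  e <- matrix(exp(rnorm(n * n, 0, spec$noise_sd)), n, n)
  (e + t(e)) / 2
}

finish_map <- function(P, spec, annotations = NULL) {
  P <- pmin(pmax(P, 0), 1)
  diag(P) <- 1
  m <- normalize_adjacent(contact_map(P, spec_region(spec)))
  if (is.null(annotations)) return(m)
  structure(c(list(map = m), annotations), class = "synthetic_map")
}

#' Synthetic interphase-like contact map
#'
#' `P[i,j] = clip(|i-j|^(-decay) * tad_factor * plaid_factor * noise, 0, 1)`
#' followed by the unit-adjacent normalization. Ground truth is returned:
#' the planted internal TAD boundaries (the last locus of each block but the
#' final one) and per-locus compartment labels.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_map`: `map` ([contact_map()]),
#'   `tad_boundaries` (planted internal split loci), `compartment_labels`.
#' @export
make_interphase_map <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_loci
  d <- abs(row(diag(n)) - col(diag(n)))
  base <- ifelse(d == 0, 1, d^(-spec$decay_exponent))
  P <- base * tad_factor_matrix(spec) * plaid_factor_matrix(spec) *
    noise_matrix(spec)
  ends <- vapply(spec$tad_blocks, `[`, numeric(1), 2)
  finish_map(P, spec, list(
    tad_boundaries = as.integer(ends[-length(ends)]),
    compartment_labels = spec$compartment_labels))
}

#' Synthetic mitotic-like contact map
#'
#' A uniform high-contact band along the diagonal (`|i-j| <= band_width`)
#' with sharp exponential decay beyond it; no TAD blocks, no plaid signal,
#' emulating the featureless locally-condensed mitotic map.
#'
#' @param spec A [synthetic_spec()].
#' @return A [contact_map()].
#' @export
make_mitotic_map <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_loci
  d <- abs(row(diag(n)) - col(diag(n)))
  P <- ifelse(d <= spec$band_width, spec$band_level,
              spec$band_level * exp(-(d - spec$band_width) / 1.5)) *
    noise_matrix(spec)
  finish_map(P, spec)
}

#' Synthetic stage series from mitotic-like to interphase-like
#'
#' Stage `k` of `n_stages` mixes the generator features at fraction
#' `t = (k-1)/(n_stages-1)`: the distance kernel blends from the mitotic
#' band to the power law, while TAD enrichment and plaid strength ramp from
#' none to their full values. The first stage equals [make_mitotic_map()]
#' and the last equals [make_interphase_map()]; insulation at the planted
#' boundaries deepens monotonically along the series.
#'
#' @param spec A [synthetic_spec()].
#' @param n_stages Number of stages (default 5).
#' @return List of [contact_map()]s with a `mixing` attribute.
#' @export
make_stage_series <- function(spec = synthetic_spec(), n_stages = 5) {
  stopifnot(n_stages >= 2)
  n <- spec$n_loci
  d <- abs(row(diag(n)) - col(diag(n)))
  band <- ifelse(d <= spec$band_width, spec$band_level,
                 spec$band_level * exp(-(d - spec$band_width) / 1.5))
  power <- ifelse(d == 0, 1, d^(-spec$decay_exponent))
  noise <- noise_matrix(spec)
  ts <- seq(0, 1, length.out = n_stages)
  maps <- lapply(ts, function(t) {
    tadf <- tad_factor_matrix(spec, 1 + t * (spec$tad_enrichment - 1))
    plaidf <- plaid_factor_matrix(spec, 1 + t * (spec$plaid_strength - 1))
    P <- ((1 - t) * band + t * power) * tadf * plaidf * noise
    finish_map(P, spec)
  })
  attr(maps, "mixing") <- ts
  maps
}

#' Equilibrium ensemble under a known bias field
#'
#' Oracle source for calibration-recovery tests: samples the chain under a
#' stage potential whose bias is known, and measures the resulting contact
#' map. Calibrating against that map should recover couplings with the same
#' effect.
#'
#' @param n_loci Chain length.
#' @param known_bias A [bias_field()] of side `n_loci`.
#' @param params A [homopolymer_params()].
#' @param settings A [langevin_settings()].
#' @param schedule An [annealing_schedule()] for the sampling runs.
#' @param n_replicas Replicas (default 8).
#' @param base_seed Seed.
#' @param record_stride Frame stride (tau).
#' @return List: `ensemble` (N x 3 x M array), `map` (measured
#'   [contact_map()]), `stage`.
#' @export
ground_truth_biased_ensemble <- function(n_loci, known_bias, params,
                                         settings = langevin_settings(),
                                         schedule = annealing_schedule(
                                           ramp_duration = 15,
                                           total_duration = 60),
                                         n_replicas = 8, base_seed = 1,
                                         record_stride = 0.5) {
  stage <- stage_potential("ground-truth", params, known_bias)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  initials <- lapply(seeds, function(s) initial_chain(n_loci, params, s))
  trajs <- run_replicas(initials, stage, settings, schedule = schedule,
                        n_replicas = n_replicas, base_seed = base_seed + 7L,
                        record_stride = record_stride)
  ensemble <- pool_ensemble(trajs, window = TRUE)
  map <- estimate_contact_probabilities(ensemble, params,
                                        region = synthetic_region(
                                          n_loci, 100))
  list(ensemble = ensemble, map = map, stage = stage)
}
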