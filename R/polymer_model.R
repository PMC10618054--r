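#' Confinement radius for a target bead volume fraction
#'
#' Beads of diameter \eqn{\sigma} occupying a sphere of radius `R` give a
#' volume fraction `n (sigma/2)^3 / R^3`. The default chromosome model
#' confines the chain so the beads fill 10% of the sphere, mimicking the
#' chromosome's share of nuclear volume; for the production-scale 510-bead
#' chain this gives `R = (510/0.1)^(1/3)/2 ~ 8.61 sigma`.
#'
#' @param n_beads Number of beads.
#' @param fraction Target volume fraction in (0, 1); default 0.10.
#' @return Confinement radius in \eqn{\sigma}.
#' @examples
#' confinement_radius_from_fraction(510, 0.10)
#' @export
confinement_radius_from_fraction <- function(n_beads, fraction = 0.10) {
  stopifnot(n_beads >= 1)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  (n_beads / fraction)^(1 / 3) / 2
}

#' Homopolymer force-field parameters
#'
#' The non-specific part of the chromosome potential: harmonic pseudo-bonds
#' between adjacent beads, a linear-placement-favoured angle term
#' `k_a (1 + cos theta)` giving the chain stiffness, a capped soft-core
#' repulsion (a Weeks--Chandler--Andersen kernel saturated at `softcore_cap`
#' so chains can pass through one another, mimicking topoisomerase activity),
#' and a half-harmonic spherical wall confining the chain to the nuclear
#' volume fraction. `contact_cutoff` and `eta` parameterize the smooth
#' contact indicator shared by the biasing potential and contact estimation.
#'
#' @param n_beads Chain length; sets the default confinement radius.
#' @param bond_length Equilibrium bond length (sigma; default 1).
#' @param bond_stiffness Bond spring constant (epsilon/sigma^2; default 100).
#' @param angle_stiffness Angle stiffness k_a (epsilon; default 2).
#' @param softcore_strength WCA energy scale (epsilon; default 1).
#' @param softcore_cap Per-pair repulsion ceiling (epsilon; default 4).
#' @param contact_cutoff Contact indicator midpoint r_c (sigma; default 1.8).
#' @param eta Contact indicator steepness (1/sigma; default 5).
#' @param volume_fraction Bead volume fraction for the default confinement
#'   radius (default 0.10).
#' @param confinement_radius Override for the wall radius (sigma).
#' @param wall_stiffness Wall spring constant (epsilon/sigma^2; default 100).
#' @return A list of class `homopolymer_params`.
#' @export
homopolymer_params <- function(n_beads,
                               bond_length = 1,
                               bond_stiffness = 100,
                               angle_stiffness = 2,
                               softcore_strength = 1,
                               softcore_cap = 4,
                               contact_cutoff = 1.8,
                               eta = 5,
                               volume_fraction = 0.10,
                               confinement_radius = NULL,
                               wall_stiffness = 100) {
  if (is.null(confinement_radius))
    confinement_radius <- confinement_radius_from_fraction(n_beads,
                                                           volume_fraction)
  p <- list(n_beads = as.integer(n_beads), bond_length = bond_length,
            bond_stiffness = bond_stiffness,
            angle_stiffness = angle_stiffness,
            softcore_strength = softcore_strength,
            softcore_cap = softcore_cap,
            contact_cutoff = contact_cutoff, eta = eta,
            confinement_radius = confinement_radius,
            wall_stiffness = wall_stiffness)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            softcore_cap > 0, is.finite(softcore_cap), contact_cutoff > 0,
            bond_stiffness >= 0, angle_stiffness >= 0, wall_stiffness >= 0)
  structure(p, class = "homopolymer_params")
}

#' Smooth contact indicator
#'
#' `f(r) = (1 + tanh(eta (r_c - r))) / 2`: a differentiable step that is 1
#' for beads well inside the contact cutoff, 1/2 exactly at the cutoff, and
#' 0 far beyond it. Its ensemble average is the simulated contact
#' probability, and the same kernel enters the biasing potential, keeping
#' calibration and measurement self-consistent.
#'
#' @param r Distance(s), sigma.
#' @param r_c Cutoff (midpoint), sigma.
#' @param eta Steepness, 1/sigma.
#' @return Values in \[0, 1\], monotone non-increasing in `r`.
#' @export
contact_indicator <- function(r, r_c = 1.8, eta = 5) {
  stopifnot(all(r >= 0))
  0.5 * (1 + tanh(eta * (r_c - r)))
}

#' Construct a max-ent bias field
#'
#' The bias field is the symmetric matrix of pairwise coupling strengths
#' `alpha_ij` (epsilon per unit contact) entering the biasing potential
#' `V_bias = sum_{i<j} alpha_ij f(r_ij)`. The diagonal and both first
#' off-diagonals are forced to zero: those contact probabilities are pinned
#' to 1 by the normalization convention and are held by the bond term, not
#' the bias.
#'
#' @param alpha Square symmetric numeric matrix (or a chain length, giving
#'   an all-zero field).
#' @return A matrix of class `bias_field`.
#' @export
bias_field <- function(alpha) {
  if (length(alpha) == 1 && is.numeric(alpha))
    alpha <- matrix(0, alpha, alpha)
  stopifnot(is.matrix(alpha), nrow(alpha) == ncol(alpha),
            all(is.finite(alpha)))
  if (max(abs(alpha - t(alpha))) > 1e-12)
    stop("bias field must be symmetric")
  alpha <- (alpha + t(alpha)) / 2
  n <- nrow(alpha)
  diag(alpha) <- 0
  if (n >= 2) {
    alpha[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 0
    alpha[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- 0
  }
  structure(alpha, class = c("bias_field", "matrix", "array"))
}

#' Bundle a stage potential
#'
#' A stage potential is the full effective energy for one cell stage: the
#' homopolymer parameters plus the Hi-C-calibrated bias field. It is the
#' object swapped by the landscape-switching protocol.
#'
#' @param label Stage name (e.g. "Prometa", "Late G1", "synthetic").
#' @param params A [homopolymer_params()].
#' @param bias A [bias_field()] whose side equals `params$n_beads`.
#' @return An object of class `stage_potential`.
#' @export
stage_potential <- function(label, params, bias = NULL) {
  stopifnot(inherits(params, "homopolymer_params"))
  if (is.null(bias)) bias <- bias_field(params$n_beads)
  if (!inherits(bias, "bias_field")) bias <- bias_field(bias)
  if (nrow(bias) != params$n_beads)
    stop(sprintf("bias side %d does not match chain length %d",
                 nrow(bias), params$n_beads))
  structure(list(label = as.character(label), params = params, bias = bias),
            class = "stage_potential")
}

#' @export
print.stage_potential <- function(x, ...) {
  cat(sprintf("<stage_potential> '%s': %d beads, R_c = %.3f sigma, %s bias\n",
              x$label, x$params$n_beads, x$params$confinement_radius,
              if (max(abs(x$bias)) == 0) "zero" else
                sprintf("|alpha| <= %.3g", max(abs(x$bias)))))
  invisible(x)
}

check_configuration <- function(conf) {
  stopifnot(is.matrix(conf), ncol(conf) == 3, nrow(conf) >= 1,
            all(is.finite(conf)))
  invisible(conf)
}

#' Homopolymer energy and analytic forces
#'
#' @param conf N x 3 coordinate matrix (sigma).
#' @param params A [homopolymer_params()].
#' @return List with `energy` (epsilon), `components` (bond, angle,
#'   softcore, wall) and `forces` (N x 3, epsilon/sigma).
#' @export
homopolymer_energy_forces <- function(conf, params) {
  check_configuration(conf)
  stopifnot(inherits(params, "homopolymer_params"))
  .cc_homopolymer_ef(conf, unclass(params))
}

#' Biasing-potential energy and analytic forces
#'
#' `V_bias = sum_{i<j} alpha_ij f(r_ij)` with the smooth contact indicator
#' `f`. Positive couplings penalize contact formation, negative couplings
#' reward it; the ensemble mean of `f` is the contact probability the
#' calibration loop matches to its target.
#'
#' @param conf N x 3 coordinate matrix.
#' @param bias A [bias_field()] of side N.
#' @param params A [homopolymer_params()] supplying `contact_cutoff`, `eta`.
#' @return List with `energy` and `forces`.
#' @export
bias_energy_forces <- function(conf, bias, params) {
  check_configuration(conf)
  if (nrow(bias) != nrow(conf))
    stop(sprintf("bias side %d does not match chain length %d",
                 nrow(bias), nrow(conf)))
  .cc_bias_ef(conf, unclass(bias), params$contact_cutoff, params$eta)
}

#' Total stage energy and forces
#'
#' The stage potential is the exact sum of the homopolymer and biasing
#' terms; energies and forces add linearly.
#'
#' @param conf N x 3 coordinate matrix.
#' @param stage A [stage_potential()].
#' @return List with `energy`, `components` and `forces`.
#' @export
total_energy_forces <- function(conf, stage) {
  stopifnot(inherits(stage, "stage_potential"))
  h <- homopolymer_energy_forces(conf, stage$params)
  b <- bias_energy_forces(conf, stage$bias, stage$params)
  list(energy = h$energy + b$energy,
       components = c(h$components, bias = b$energy),
       forces = h$forces + b$forces)
}

#' Serialize a stage potential to a text archive
#'
#' A single plain-text file: `key = value` header lines (with a
#' `format_version` field) followed by the dense bias matrix.
#'
#' @param stage A [stage_potential()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_potential <- function(stage, path) {
  stopifnot(inherits(stage, "stage_potential"))
  p <- stage$params
  hdr <- c("format_version = 1",
           sprintf("label = %s", stage$label),
           sprintf("%s = %.17g", names(unclass(p)),
                   as.numeric(unclass(p))))
  body <- apply(unclass(stage$bias), 1,
                function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, "alpha:", body), path)
  invisible(path)
}

#' Read a stage potential text archive
#'
#' @param path Path written by [write_stage_potential()].
#' @return A [stage_potential()].
#' @export
read_stage_potential <- function(path) {
  lines <- readLines(path)
  sep <- match("alpha:", lines)
  if (is.na(sep)) stop("malformed stage archive: no alpha section")
  hdr <- lines[seq_len(sep - 1)]
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  if (vals[keys == "format_version"] != "1")
    stop("unsupported stage archive version")
  label <- vals[keys == "label"]
  num <- setNames(as.list(as.numeric(vals[-(1:2)])), keys[-(1:2)])
  params <- do.call(homopolymer_params, num)
  alpha <- do.call(rbind, lapply(lines[-seq_len(sep)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stage_potential(label, params, bias_field(alpha))
}
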