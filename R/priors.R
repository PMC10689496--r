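#' Fossilized birth-death parameters
#'
#' @param lambda speciation (language birth) rate, per year, > 0
#' @param mu extinction rate, per year, >= 0
#' @param psi through-time sampling rate for non-extant tips, >= 0 (may be 0
#'   only when every tip is extant)
#' @param rho sampling probability of extant tips, in (0, 1]
#' @return object of class `fbd_params`
#' @export
fbd_params <- function(lambda, mu = 0, psi = 0, rho = 1) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (mu < 0 || psi < 0) stop("mu and psi must be >= 0", call. = FALSE)
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]", call. = FALSE)
  structure(list(lambda = lambda, mu = mu, psi = psi, rho = rho),
            class = "fbd_params")
}

fbd_c1 <- function(p) sqrt((p$lambda - p$mu - p$psi)^2 + 4 * p$lambda * p$psi)

fbd_c2 <- function(p) {
  -(p$lambda - p$mu - 2 * p$lambda * p$rho - p$psi) / fbd_c1(p)
}

fbd_log_q <- function(t, p) {
  c1 <- fbd_c1(p); c2 <- fbd_c2(p)
  log(4) - log(2 * (1 - c2^2) + exp(-c1 * t) * (1 - c2)^2 +
                 exp(c1 * t) * (1 + c2)^2)
}

fbd_p0 <- function(t, p) {
  c1 <- fbd_c1(p); c2 <- fbd_c2(p)
  (p$lambda + p$mu + p$psi +
     c1 * (exp(-c1 * t) * (1 - c2) - (1 + c2)) /
       (exp(-c1 * t) * (1 - c2) + (1 + c2))) / (2 * p$lambda)
}

#' Fossilized birth-death log prior density of a dated tree
#'
#' Density of the node ages and sampled tips of a fixed-topology dated tree
#' under the fossilized birth-death process, conditioned on the root age and
#' not on survival, so that with `mu = psi = 0, rho = 1` it reduces exactly
#' to the Yule closed form
#' `(n - 2) log(lambda) - lambda (2 x_root + sum(other node ages))`.
#' Non-extant (dated) tips require `psi > 0` and contribute the
#' `psi p0(y) / q(y)` fossil-tip factor.
#'
#' @param tree dated `phylo` (tips at their sampling ages; extant tips at 0)
#' @param p an [fbd_params()]
#' @param extant_age tips at or below this age (years BP) count as extant
#' @return log prior density.
#' @export
fbd_log_density <- function(tree, p, extant_age = 1e-8) {
  stopifnot(inherits(p, "fbd_params"))
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  tip_ages <- ages[seq_len(ntip)]
  node_ages_int <- ages[(ntip + 1):(ntip + tree$Nnode)]
  extant <- tip_ages <= extant_age
  fossil <- which(!extant)
  if (length(fossil) && p$psi == 0) {
    stop("psi = 0 with a non-extant tip present", call. = FALSE)
  }
  root_age <- max(node_ages_int)
  others <- node_ages_int[-which.max(node_ages_int)]
  ld <- 2 * fbd_log_q(root_age, p) +
    sum(log(p$lambda) + fbd_log_q(others, p)) +
    sum(extant) * log(p$rho)
  if (length(fossil)) {
    ld <- ld + sum(log(p$psi) + log(pmax(fbd_p0(tip_ages[fossil], p), 0)) -
                     fbd_log_q(tip_ages[fossil], p))
  }
  ld
}

#' Calibrations for tip-dated inference
#'
#' @param tip_calibrations named numeric vector of fixed tip ages (years BP);
#'   languages absent from it are extant (0 BP)
#' @param node_calibrations list of node calibrations, each
#'   `list(tips = <chr>, mean = <years BP>, sigma = <years>)`: a normal prior
#'   on the age of the most recent common ancestor of `tips`, whose
#'   monophyly is enforced during inference.
#' @return object of class `calibration_set`
#' @export
calibration_set <- function(tip_calibrations = NULL, node_calibrations = list()) {
  for (cal in node_calibrations) {
    stopifnot(length(cal$tips) >= 2, cal$sigma > 0)
  }
  structure(list(tips = tip_calibrations, nodes = node_calibrations),
            class = "calibration_set")
}
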