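#' Specification for a synthetic modular connectome
#'
#' Describes a weighted modular connectome with geometric fiber lengths.
#' Nodes are split into two mirrored "hemisphere" blocks of 3-D coordinates;
#' fiber lengths are Euclidean distances between node coordinates, which at
#' the default box size gives mean lengths in the tens-of-millimetres range
#' typical of cortico-cortical fibers. Module structure is planted by
#' connecting within-module node pairs with probability `intra_density` and
#' between-module pairs with probability `inter_density`; weights are
#' log-normal.
#'
#' @param n_nodes number of nodes (default 114).
#' @param n_modules number of planted modules (default 4).
#' @param intra_density,inter_density edge probabilities within/between
#'   modules; `0 < inter_density <= intra_density <= 1`.
#' @param weight_lognormal_params `c(meanlog, sdlog)` of edge weights.
#' @param coordinate_box extents (mm) of one hemisphere block, `c(x, y, z)`.
#' @param seed integer seed.
#' @return A `synthetic_connectome_spec` list.
#' @export
synthetic_connectome_spec <- function(n_nodes = 114, n_modules = 4,
                                      intra_density = 0.5,
                                      inter_density = 0.1,
                                      weight_lognormal_params = c(0, 1),
                                      coordinate_box = c(60, 140, 100),
                                      seed = 1) {
  if (n_modules < 1) stop("n_modules must be >= 1")
  if (!(inter_density > 0 && inter_density <= intra_density &&
        intra_density <= 1))
    stop("need 0 < inter_density <= intra_density <= 1")
  if (n_nodes < 2 * n_modules) stop("too few nodes for the module count")
  structure(list(n_nodes = n_nodes, n_modules = n_modules,
                 intra_density = intra_density, inter_density = inter_density,
                 weight_lognormal_params = weight_lognormal_params,
                 coordinate_box = coordinate_box, seed = seed),
            class = "synthetic_connectome_spec")
}

#' Generate a synthetic modular connectome
#'
#' Draws node coordinates in two mirrored hemisphere blocks, plants modules
#' spanning both hemispheres, samples edges and log-normal weights, assigns
#' Euclidean fiber lengths, and normalizes weights to unit mean non-zero
#' edge weight. Every node is guaranteed at least one edge.
#'
#' @param spec a [synthetic_connectome_spec()].
#' @return A [structural_connectome()] whose `system_labels` carry the
#'   planted module identities, with attribute `modules` (integer vector).
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_connectome_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  box <- spec$coordinate_box
  hemi <- rep(c("L", "R"), length.out = n)
  coords <- matrix(stats::runif(3 * n), n, 3)
  coords <- sweep(coords, 2, box, `*`)
  # mirror: left block at x in [-box_x - 5, -5], right at [5, box_x + 5]
  coords[, 1] <- ifelse(hemi == "L", -coords[, 1] - 5, coords[, 1] + 5)
  modules <- rep(seq_len(spec$n_modules), length.out = n)
  p <- ifelse(outer(modules, modules, `==`),
              spec$intra_density, spec$inter_density)
  edge <- matrix(FALSE, n, n)
  up <- upper.tri(edge)
  edge[up] <- stats::runif(sum(up)) < p[up]
  edge <- edge | t(edge)
  # no isolated nodes: attach to a random same-module partner
  for (i in which(rowSums(edge) == 0)) {
    cand <- setdiff(which(modules == modules[i]), i)
    if (length(cand) == 0) cand <- setdiff(seq_len(n), i)
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    edge[i, j] <- edge[j, i] <- TRUE
  }
  w <- matrix(0, n, n)
  m <- sum(edge[up])
  wv <- stats::rlnorm(m, spec$weight_lognormal_params[1],
                      spec$weight_lognormal_params[2])
  w[up][edge[up]] <- wv
  w <- w + t(w)
  d <- as.matrix(stats::dist(coords))
  lengths <- d * (w > 0)
  sysnames <- c("CON", "DMN", "LIM", "DAN", "VAN", "SMN", "VIS")
  labels <- sysnames[((modules - 1) %% length(sysnames)) + 1]
  sc <- structural_connectome(w, lengths,
                              node_ids = sprintf("n%03d", seq_len(n)),
                              system_labels = labels, hemisphere = hemi)
  sc <- normalize_weights(sc)
  attr(sc, "modules") <- modules
  attr(sc, "coordinates") <- coords
  sc
}

#' Specification for synthetic state-switching BOLD
#'
#' Reference ("empirical-like") BOLD with a planted hidden-Markov state
#' structure: a state path is sampled per TR from `markov_transition`, and
#' each volume is drawn from the current state's multivariate Gaussian plus
#' white observation noise.
#'
#' If `states` is `NULL`, two states are built from a shared modular
#' correlation skeleton: a *segregated* state with strong within-module and
#' weak between-module correlation, and an *integrated* state whose modules
#' are permeable (substantial between-module correlation while staying
#' detectable), so the integrated state has the larger mean participation
#' coefficient by construction.
#'
#' @param n_nodes number of regions.
#' @param n_timepoints volumes per run (default 1200).
#' @param tr_seconds repetition time (default 0.72).
#' @param states list of `list(covariance =, label =)`; `NULL` builds the
#'   default two-state set.
#' @param n_modules modules used by the default state builder.
#' @param segregation_strength within-module correlation contrast of the
#'   default segregated state, in (0, 1) (default 0.55).
#' @param markov_transition S x S row-stochastic matrix; `NULL` gives a
#'   2-state chain with mean dwell time ~120 s at the given TR (comfortably
#'   above the ~47-s analysis window, so most windows are state-pure).
#' @param observation_noise_sd white noise SD added to every sample.
#' @param seed integer seed.
#' @return A `synthetic_bold_spec` list.
#' @export
synthetic_bold_spec <- function(n_nodes = 40, n_timepoints = 1200,
                                tr_seconds = 0.72, states = NULL,
                                n_modules = 4, segregation_strength = 0.55,
                                markov_transition = NULL,
                                observation_noise_sd = 0.2, seed = 1) {
  if (is.null(states))
    states <- default_bold_states(n_nodes, n_modules, segregation_strength)
  S <- length(states)
  if (is.null(markov_transition)) {
    dwell_trs <- 120 / tr_seconds
    p_stay <- 1 - 1 / dwell_trs
    markov_transition <- matrix((1 - p_stay) / (S - 1), S, S)
    diag(markov_transition) <- p_stay
  }
  if (nrow(markov_transition) != S || ncol(markov_transition) != S)
    stop("markov_transition must be S x S")
  if (any(abs(rowSums(markov_transition) - 1) > 1e-9))
    stop("markov_transition rows must sum to 1")
  for (st in states) {
    if (any(dim(st$covariance) != n_nodes))
      stop("state covariance dimension mismatch")
    ch <- try(chol(st$covariance), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("state covariance is not positive definite: ", st$label)
  }
  structure(list(n_nodes = n_nodes, n_timepoints = n_timepoints,
                 tr_seconds = tr_seconds, states = states,
                 markov_transition = markov_transition,
                 observation_noise_sd = observation_noise_sd, seed = seed),
            class = "synthetic_bold_spec")
}

# two-state covariance builder: shared modular skeleton, segregation knob.
# Both states keep detectable modules (so community detection finds the
# same skeleton); they differ in how much correlation crosses module
# boundaries, which is what moves the participation coefficient.
default_bold_states <- function(n_nodes, n_modules, seg) {
  modules <- rep(seq_len(n_modules), length.out = n_nodes)
  same <- outer(modules, modules, `==`)
  seg_cov <- ifelse(same, 0.1 + seg, 0.05)   # sharp modules: low P
  int_cov <- ifelse(same, 0.45, 0.30)        # permeable modules: high P
  diag(seg_cov) <- diag(int_cov) <- 1
  list(list(covariance = seg_cov, label = "segregated", modules = modules),
       list(covariance = int_cov, label = "integrated", modules = modules))
}

#' Generate state-switching reference BOLD
#'
#' @param spec a [synthetic_bold_spec()].
#' @return A list with `bold` (a [bold_dataset()]) and `true_states`
#'   (character vector of per-TR state labels).
#' @export
generate_state_bold <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bold_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes; T <- spec$n_timepoints
  S <- length(spec$states)
  chols <- lapply(spec$states, function(st) chol(st$covariance))
  path <- integer(T)
  path[1] <- sample.int(S, 1)
  for (t in 2:T)
    path[t] <- sample.int(S, 1, prob = spec$markov_transition[path[t - 1], ])
  x <- matrix(0, n, T)
  z <- matrix(stats::rnorm(n * T), n, T)
  for (t in seq_len(T))
    x[, t] <- drop(crossprod(chols[[path[t]]], z[, t]))
  x <- x + spec$observation_noise_sd * matrix(stats::rnorm(n * T), n, T)
  labels <- vapply(spec$states, `[[`, "", "label")
  list(bold = bold_dataset(x, spec$tr_seconds, run_label = "synthetic"),
       true_states = labels[path])
}
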