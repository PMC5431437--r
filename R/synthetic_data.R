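# Synthetic-data generators with planted ground truth, so that the screen,
# the consensus filter, the network statistics and the formula comparison can
# all be exercised end-to-end without any external data.
#
# The default configuration mirrors the study's headline scenario: 66
# candidate compounds over seven herbs, 139 targets in the comparison union,
# 135 of them shared, 4 specific to the removed component set and none of
# those disease-linked.

.default_herbs <- c("Gymnadenia Conopsea" = 11, "Stigma Croci" = 8,
                    "Myristica Semena" = 11, "Semen Strychni" = 12,
                    "Boswellia" = 9, "Syringa Oblata" = 7,
                    "Rhizoma Alpiniae Officinarum" = 15)

check_two_component <- function(spec, lo_bound, hi_bound, threshold, what) {
  ok <- is.list(spec) && all(c("p_high", "low", "high") %in% names(spec)) &&
    is.numeric(spec$p_high) && length(spec$p_high) == 1L &&
    spec$p_high >= 0 && spec$p_high <= 1 &&
    is.numeric(spec$low) && length(spec$low) == 2L &&
    is.numeric(spec$high) && length(spec$high) == 2L
  if (!ok) {
    stop("config error: ", what,
         " must be list(p_high, low = c(min, max), high = c(min, max))")
  }
  for (side in c("low", "high")) {
    r <- spec[[side]]
    if (r[1] > r[2] || r[1] < lo_bound || r[2] > hi_bound) {
      stop("config error: ", what, "$", side, " out of range")
    }
    # a component collapsed onto the filter threshold makes the planted
    # pass/fail label meaningless
    if (r[1] == r[2] && r[1] == threshold) {
      stop("config error: ", what, "$", side,
           " has zero spread exactly on the threshold ", threshold)
    }
  }
  invisible(TRUE)
}

#' Configuration for the synthetic-data generators
#'
#' OB and DL are drawn from two-component mixtures of uniform ranges sitting
#' (by default) on either side of the screening thresholds (30% OB, 0.18 DL),
#' so the design strict-pass rate is computable in closed form from the
#' mixture weights and range overlaps. Interaction scores are drawn so that
#' planted true interactions clear both consensus cutoffs by at least
#' `score_noise` while decoys miss at least one cutoff by at least the same
#' margin.
#'
#' @param seed integer seed; all generators are fully deterministic given it.
#' @param n_compounds number of compounds to simulate (default 66).
#' @param n_targets number of targets (default 139).
#' @param herbs named numeric vector of herb allocation weights (default: the
#'   seven herbs of the modified formula, weighted by their published
#'   candidate counts).
#' @param multi_herb_rate probability that a compound is attributed to a
#'   second herb (default 0.1, echoing the handful of multi-herb rows in the
#'   published table).
#' @param ob_distribution,dl_distribution two-component specs
#'   `list(p_high, low = c(min, max), high = c(min, max))` of uniform ranges;
#'   `p_high` is the weight of the `high` component.
#' @param true_interaction_rate fraction of compound-target pairs planted as
#'   true interactions (default 0.05).
#' @param score_noise margin by which true scores clear, and failing decoy
#'   scores miss, the consensus cutoffs (default 0.02).
#' @param planted_shared_fraction fraction of the target union shared by the
#'   two formula-variant networks (default 135/139).
#' @param n_b_specific number of targets specific to the removed component
#'   set (default 4).
#' @param n_disease_linked_b_specific how many of those are disease-linked
#'   (default 0).
#' @param noise_targets number of targets whose planted class is randomly
#'   perturbed in [generate_formula_pair()]; 0 (default) is the noise-free
#'   mode in which the planted shared fraction is recovered exactly.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              n_compounds = 66,
                              n_targets = 139,
                              herbs = NULL,
                              multi_herb_rate = 0.1,
                              ob_distribution = list(p_high = 0.85,
                                                     low = c(2, 28),
                                                     high = c(32, 95)),
                              dl_distribution = list(p_high = 0.85,
                                                     low = c(0.01, 0.17),
                                                     high = c(0.19, 0.95)),
                              true_interaction_rate = 0.05,
                              score_noise = 0.02,
                              planted_shared_fraction = 135 / 139,
                              n_b_specific = 4,
                              n_disease_linked_b_specific = 0,
                              noise_targets = 0) {
  if (!is_count(seed) || seed >= 2^31) {
    stop("config error: seed must be a non-negative 32-bit integer")
  }
  if (!is_count(n_compounds, allow_zero = FALSE) ||
      !is_count(n_targets, allow_zero = FALSE)) {
    stop("config error: n_compounds and n_targets must be positive counts")
  }
  herbs <- herbs %||% .default_herbs
  if (is.null(names(herbs)) || any(!nzchar(names(herbs))) ||
      anyDuplicated(names(herbs)) || any(herbs <= 0)) {
    stop("config error: herbs must be uniquely named positive weights")
  }
  fracs <- c(multi_herb_rate = multi_herb_rate,
             true_interaction_rate = true_interaction_rate,
             planted_shared_fraction = planted_shared_fraction)
  if (any(!is.finite(fracs)) || any(fracs < 0 | fracs > 1)) {
    stop("config error: rates/fractions must lie in [0, 1]")
  }
  check_two_component(ob_distribution, 0, 100, 30, "ob_distribution")
  check_two_component(dl_distribution, 0, 1, 0.18, "dl_distribution")
  if (!is.numeric(score_noise) || length(score_noise) != 1L ||
      score_noise < 0 || score_noise >= 0.2) {
    stop("config error: score_noise must lie in [0, 0.2)")
  }
  if (!is_count(n_b_specific) || !is_count(n_disease_linked_b_specific) ||
      !is_count(noise_targets)) {
    stop("config error: target counts must be non-negative integers")
  }
  if (n_disease_linked_b_specific > n_b_specific) {
    stop("config error: n_disease_linked_b_specific exceeds n_b_specific")
  }
  n_shared <- round(planted_shared_fraction * n_targets)
  if (n_shared + n_b_specific > n_targets) {
    stop("config error: planted_shared_fraction and n_b_specific ",
         "inconsistent with n_targets")
  }
  structure(list(seed = as.integer(seed), n_compounds = n_compounds,
                 n_targets = n_targets, herbs = herbs,
                 multi_herb_rate = multi_herb_rate,
                 ob_distribution = ob_distribution,
                 dl_distribution = dl_distribution,
                 true_interaction_rate = true_interaction_rate,
                 score_noise = score_noise,
                 planted_shared_fraction = planted_shared_fraction,
                 n_b_specific = n_b_specific,
                 n_disease_linked_b_specific = n_disease_linked_b_specific,
                 noise_targets = noise_targets),
            class = "simulation_config")
}

draw_mixture <- function(n, spec) {
  high <- stats::runif(n) < spec$p_high
  lo <- ifelse(high, spec$high[1], spec$low[1])
  hi <- ifelse(high, spec$high[2], spec$low[2])
  stats::runif(n, lo, hi)
}

# probability that one draw from a two-component uniform mixture lands at or
# above `threshold` (used by tests as the design pass rate)
mixture_pass_prob <- function(spec, threshold) {
  frac_above <- function(r) {
    if (threshold <= r[1]) 1
    else if (threshold >= r[2]) 0
    else (r[2] - threshold) / (r[2] - r[1])
  }
  spec$p_high * frac_above(spec$high) +
    (1 - spec$p_high) * frac_above(spec$low)
}

#' Generate a synthetic compound library with known filter labels
#'
#' @param config a [simulation_config()].
#' @return list with `library` (a [compound_library()]) and `truth`
#'   (data.frame `compound_id`, `ob_pass`, `dl_pass`, `strict_pass` recording
#'   each compound's true status against the default 30 / 0.18 thresholds).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  ids <- sprintf("C%04d", seq_len(n))
  herb_names <- names(config$herbs)
  w <- config$herbs / sum(config$herbs)
  first <- sample(herb_names, n, replace = TRUE, prob = w)
  herbs <- lapply(seq_len(n), function(i) {
    h <- first[i]
    if (length(herb_names) > 1L && stats::runif(1) < config$multi_herb_rate) {
      h <- c(h, sample(setdiff(herb_names, h), 1L))
    }
    h
  })
  ob <- draw_mixture(n, config$ob_distribution)
  dl <- draw_mixture(n, config$dl_distribution)
  lib <- compound_library(compound_id = ids,
                          name = paste0("synthetic-", ids),
                          ob = ob, dl = dl, herbs = herbs)
  truth <- data.frame(compound_id = ids,
                      ob_pass = ob >= 30, dl_pass = dl >= 0.18,
                      stringsAsFactors = FALSE)
  truth$strict_pass <- truth$ob_pass & truth$dl_pass
  list(library = lib, truth = truth)
}

#' Generate a synthetic compound-target score table with planted truth
#'
#' Every compound-target pair receives RF and SVM scores: planted true
#' interactions clear both consensus cutoffs (RF > 0.7, SVM > 0.8) by at
#' least `score_noise`; decoys miss at least one cutoff by at least the same
#' margin. [consensus_filter()] at default thresholds therefore recovers the
#' truth set exactly.
#'
#' @param library a [compound_library()] (e.g. from [generate_library()]).
#' @param targets character vector of target ids; default
#'   `sprintf("T%03d", 1:n_targets)` from the config.
#' @param config a [simulation_config()].
#' @return list with `scores` (data.frame `compound_id`, `target_id`,
#'   `rf_score`, `svm_score`) and `truth` (same rows plus logical `is_true`).
#' @export
generate_scores <- function(library, targets = NULL, config) {
  stopifnot(inherits(library, "compound_library"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  targets <- targets %||% sprintf("T%03d", seq_len(config$n_targets))
  grid <- expand.grid(compound_id = library$compound_id,
                      target_id = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  is_true <- stats::runif(m) < config$true_interaction_rate
  eps <- config$score_noise
  rf <- numeric(m)
  svm <- numeric(m)
  n_true <- sum(is_true)
  rf[is_true] <- stats::runif(n_true, 0.7 + eps, 1)
  svm[is_true] <- stats::runif(n_true, 0.8 + eps, 1)
  n_decoy <- m - n_true
  if (n_decoy > 0) {
    fail_rf <- stats::runif(n_decoy) < 0.5
    rf_d <- ifelse(fail_rf,
                   stats::runif(n_decoy, 0, 0.7 - eps),
                   stats::runif(n_decoy, 0, 1))
    svm_d <- ifelse(fail_rf,
                    stats::runif(n_decoy, 0, 1),
                    stats::runif(n_decoy, 0, 0.8 - eps))
    rf[!is_true] <- rf_d
    svm[!is_true] <- svm_d
  }
  scores <- data.frame(grid, rf_score = rf, svm_score = svm,
                       stringsAsFactors = FALSE)
  truth <- data.frame(grid, is_true = is_true, stringsAsFactors = FALSE)
  list(scores = scores, truth = truth)
}

#' Generate a pair of formula-variant networks with a planted shared fraction
#'
#' Builds two bipartite networks over a common target universe: network A
#' (the retained formula) covers the shared and A-specific targets, network B
#' (the removed component set) covers the shared and B-specific targets.
#' `n_shared = round(planted_shared_fraction * n_targets)` targets are
#' shared; `n_b_specific` are B-only (the first
#' `n_disease_linked_b_specific` of them annotated disease-linked, the rest
#' not); the remainder are A-specific. In noise-free mode
#' (`noise_targets = 0`) [compare_formulae()] recovers the planted fraction
#' exactly; with `noise_targets > 0` that many randomly chosen shared targets
#' are dropped from one randomly chosen side, perturbing the fraction.
#'
#' @param config a [simulation_config()].
#' @return list with `net_a`, `net_b` (`ct_network`s), `annotations`
#'   (data.frame `target_id`, `disease_associated`) and `truth`
#'   (list `shared`, `a_specific`, `b_specific`, `shared_fraction`).
#' @export
generate_formula_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n_t <- config$n_targets
  targets <- sprintf("T%03d", seq_len(n_t))
  n_shared <- round(config$planted_shared_fraction * n_t)
  n_b <- config$n_b_specific
  perm <- sample(targets)   # random class assignment, deterministic in seed
  shared <- sort(perm[seq_len(n_shared)])
  b_specific <- sort(perm[n_shared + seq_len(n_b)])
  a_specific <- sort(setdiff(targets, c(shared, b_specific)))

  n_ca <- config$n_compounds
  n_cb <- max(2L, round(config$n_compounds / 2))
  comp_a <- sprintf("A%03d", seq_len(n_ca))
  comp_b <- sprintf("B%03d", seq_len(n_cb))
  link <- function(tgts, comps) {
    if (!length(tgts)) {
      return(data.frame(compound_id = character(), target_id = character(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(tgts, function(t) {
      k <- sample(1:3, 1L)
      data.frame(compound_id = sample(comps, min(k, length(comps))),
                 target_id = t, stringsAsFactors = FALSE)
    }))
  }
  edges_a <- link(c(shared, a_specific), comp_a)
  edges_b <- link(c(shared, b_specific), comp_b)
  if (config$noise_targets > 0 && length(shared)) {
    drop <- sample(shared, min(config$noise_targets, length(shared)))
    from_a <- stats::runif(length(drop)) < 0.5
    edges_a <- edges_a[!(edges_a$target_id %in% drop[from_a]), , drop = FALSE]
    edges_b <- edges_b[!(edges_b$target_id %in% drop[!from_a]), , drop = FALSE]
  }
  groups_a <- stats::setNames(rep(list("modified formula"), n_ca), comp_a)
  groups_b <- stats::setNames(rep(list("removed components"), n_cb), comp_b)
  net_a <- build_network(edges_a, groups = groups_a)
  net_b <- build_network(edges_b, groups = groups_b)
  disease <- rep(TRUE, n_t)
  names(disease) <- targets
  disease[b_specific] <- seq_along(b_specific) <=
    config$n_disease_linked_b_specific
  annotations <- data.frame(target_id = targets,
                            disease_associated = unname(disease),
                            stringsAsFactors = FALSE)
  list(net_a = net_a, net_b = net_b, annotations = annotations,
       truth = list(shared = shared, a_specific = a_specific,
                    b_specific = b_specific,
                    shared_fraction = n_shared / n_t))
}
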