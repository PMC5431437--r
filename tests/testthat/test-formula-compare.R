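net_from <- function(targets, prefix = "c", group = "g") {
  if (length(targets) == 0L) {
    return(build_network(data.frame(compound_id = character(),
                                    target_id = character())))
  }
  edges <- data.frame(compound_id = paste0(prefix, seq_along(targets) %% 3),
                      target_id = targets, stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(list(group), length(unique(edges$compound_id))),
                            unique(edges$compound_id))
  build_network(edges, groups = groups)
}

annot <- function(targets, disease) {
  data.frame(target_id = targets, disease_associated = disease,
             stringsAsFactors = FALSE)
}

test_that("identical and disjoint networks give the extreme shared fractions", {
  t <- paste0("t", 1:10)
  same <- compare_formulae(net_from(t), net_from(t, "d"),
                           annot(t, TRUE))
  expect_equal(same$shared_fraction, 1.0)
  expect_length(same$a_specific, 0)
  expect_length(same$b_specific, 0)
  expect_true(removal_verdict(same, 1.0)$removable)

  disjoint <- compare_formulae(net_from(paste0("a", 1:5)),
                               net_from(paste0("b", 1:5), "d"))
  expect_equal(disjoint$shared_fraction, 0.0)
  expect_length(disjoint$shared_targets, 0)

  expect_error(compare_formulae(net_from(character()),
                                net_from(character())),
               "domain error")
})

test_that("the headline scenario (139 targets, 4 removed-specific, none disease-linked) is removable", {
  shared <- sprintf("s%03d", 1:135)
  b_only <- sprintf("x%d", 1:4)
  net_a <- net_from(shared, "m")
  net_b <- net_from(c(shared, b_only), "r")
  ann <- annot(c(shared, b_only), c(rep(TRUE, 135), rep(FALSE, 4)))
  cmp <- compare_formulae(net_a, net_b, ann)
  expect_equal(cmp$shared_fraction, 135 / 139, tolerance = 1e-12)
  expect_length(cmp$b_specific, 4)
  expect_length(cmp$b_specific_disease_linked, 0)
  v <- removal_verdict(cmp, 0.90)
  expect_true(v$removable)
  expect_equal(v$status, "removable")
  expect_true(v$reasons$coverage$pass)
  expect_true(v$reasons$disease_link$pass)
})

test_that("any disease-linked removed-specific target blocks removal", {
  shared <- paste0("s", 1:20)
  cmp <- compare_formulae(
    net_from(shared, "m"), net_from(c(shared, "bad"), "r"),
    annot(c(shared, "bad"), c(rep(FALSE, 20), TRUE)))
  v <- removal_verdict(cmp)
  expect_false(v$removable)
  expect_equal(v$status, "not removable")
  expect_false(v$reasons$disease_link$pass)
})

test_that("unknown disease status yields indeterminate, not a silent pass", {
  shared <- paste0("s", 1:20)
  cmp <- compare_formulae(net_from(shared, "m"),
                          net_from(c(shared, "mys"), "r"),
                          annot(shared, TRUE))   # "mys" unannotated
  expect_equal(cmp$b_specific_unknown, "mys")
  v <- removal_verdict(cmp)
  expect_true(is.na(v$removable))
  expect_equal(v$status, "indeterminate")
  # but a failed coverage rule dominates: verdict is a definite no
  v2 <- removal_verdict(cmp, shared_fraction_threshold = 0.999)
  expect_false(v2$removable)
})

test_that("verdict is monotone in shared fraction and disease-linked count", {
  shared <- paste0("s", 1:18)
  b_only <- paste0("x", 1:2)
  cmp <- compare_formulae(net_from(shared, "m"),
                          net_from(c(shared, b_only), "r"),
                          annot(c(shared, b_only),
                                c(rep(TRUE, 18), FALSE, FALSE)))
  # increasing the threshold can only flip removable -> not removable
  verdicts <- vapply(c(0.5, 0.8, 0.9, 0.95), function(th) {
    isTRUE(removal_verdict(cmp, th)$removable)
  }, logical(1))
  expect_true(all(diff(as.integer(verdicts)) <= 0))
})

test_that("original-vs-modified comparison mirrors the published structure", {
  modified <- paste0("t", 1:60)
  original <- c(modified, paste0("o", 1:4))   # superset, 4 original-only
  ann <- annot(original, c(rep(TRUE, 60), rep(FALSE, 4)))
  cmp <- compare_original_vs_modified(net_from(modified, "m"),
                                      net_from(original, "o"), ann)
  expect_equal(cmp$labels, c("modified", "original"))
  expect_length(cmp$b_specific, 4)
  expect_length(cmp$b_specific_disease_linked, 0)
  expect_true(removal_verdict(cmp)$removable)

  # modified a strict superset: specifics land on the a side
  rev <- compare_original_vs_modified(net_from(original, "m"),
                                      net_from(modified, "o"), ann)
  expect_length(rev$a_specific, 4)
  expect_length(rev$b_specific, 0)
})

test_that("partition equals a brute-force per-target scan on random pairs", {
  set.seed(77)
  for (rep in 1:10) {
    universe <- paste0("t", 1:25)
    ta <- sample(universe, sample(5:20, 1))
    tb <- sample(universe, sample(5:20, 1))
    cmp <- compare_formulae(net_from(ta, "m"), net_from(tb, "r"))
    for (t in union(ta, tb)) {
      in_a <- t %in% ta; in_b <- t %in% tb
      if (in_a && in_b) expect_true(t %in% cmp$shared_targets)
      else if (in_a) expect_true(t %in% cmp$a_specific)
      else expect_true(t %in% cmp$b_specific)
    }
    expect_equal(length(cmp$shared_targets) + length(cmp$a_specific) +
                   length(cmp$b_specific), length(union(ta, tb)))
  }
})
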