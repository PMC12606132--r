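toy_table <- function(scores, task) {
  score_table(sprintf("psm%d", seq_len(nrow(scores))), scores, task)
}

# Straight transcription of the consensus voting rule, used as the oracle.
oracle_consensus <- function(scores, direction, n, tail) {
  models <- colnames(scores)
  ranked <- sapply(models, function(m) {
    sort(scores[, m], decreasing = (tail == "top"))[1:n]
  })
  votes <- setNames(integer(length(models)), models)
  for (pos in 1:n) {
    v <- ranked[pos, ]
    opt <- if (direction == "higher") max(v) else min(v)
    winner <- sort(names(v)[v == opt])[1]
    votes[winner] <- votes[winner] + 1L
  }
  votes
}

test_that("per-file search subsets follow the floor(budget/P) rule", {
  w <- tiny_world()
  sims <- lapply(1:3, function(s) simulate_dataset(w, 40, seed = s))
  pins <- lapply(sims, `[[`, "pin")
  got2 <- select_search_psms(pins[1:2], 60)
  expect_length(got2, 60)  # 30 per file
  got3 <- select_search_psms(pins, 100)
  expect_length(got3, 99)  # floor(100/3) = 33 per file
  # P = 1 matches the pooled top selection
  one <- select_search_psms(pins[1], 25)
  pooled <- select_top_psms(pins[1], 25)
  expect_equal(vapply(one, `[[`, character(1), "spec_id"),
               vapply(pooled, `[[`, character(1), "spec_id"))
  # within-file subsets really are that file's lowest e-values
  ev1 <- sort(vapply(pins[[1]]$records, `[[`, numeric(1), "evalue"))[1:30]
  got_ev <- sort(vapply(got2[1:30], `[[`, numeric(1), "evalue"))
  expect_equal(got_ev, ev1)
})

test_that("median pick optimizes its statistic in both directions", {
  ms2 <- toy_table(cbind(A = c(0.9, 0.9, 0.9), B = c(0.7, 0.7, 0.7)), "MS2")
  expect_equal(pick_median(ms2)$chosen, "A")
  rt <- toy_table(cbind(A = c(2, 2, 2), B = c(1.4, 1.4, 1.4)), "RT")
  expect_equal(pick_median(rt)$chosen, "B")
  tie <- toy_table(cbind(B = c(1, 2, 3), A = c(2, 1, 3)), "MS2")
  expect_equal(pick_median(tie)$chosen, "A")  # lexicographic tie-break
})

test_that("consensus votes match the worked example and bound cases", {
  # RT task, two models, n = 3: sorted-descending deviations
  # A: (5,4,3), B: (6,2,1); smaller deviation wins each position
  rt <- toy_table(cbind(A = c(5, 4, 3), B = c(6, 2, 1)), "RT")
  rep <- pick_top_consensus(rt, 3)
  expect_equal(unname(rep$votes[c("A", "B")]), c(1L, 2L))
  expect_equal(rep$chosen, "B")
  expect_equal(sum(rep$votes), 3)
  expect_equal(unname(rep$per_model_statistic["B"]), 2 / 3)

  # dominance: all votes, fraction 1
  ms2 <- toy_table(cbind(A = c(0.9, 0.8, 0.7), B = c(0.5, 0.4, 0.3)), "MS2")
  repd <- pick_top_consensus(ms2, 3)
  expect_equal(unname(repd$votes[["A"]]), 3L)
  expect_equal(unname(repd$per_model_statistic[["A"]]), 1)
  expect_equal(unname(repd$per_model_statistic[["B"]]), 0)

  # identical columns: every position ties, median tie-break applies
  same <- toy_table(cbind(A = c(1, 2, 3), B = c(1, 2, 3)), "MS2")
  expect_equal(pick_bottom_consensus(same, 2)$chosen, "A")

  # bottom consensus rewards the better lower tail
  low <- toy_table(cbind(A = c(0.5, 0.6, 0.9), B = c(0.2, 0.3, 0.95)), "MS2")
  expect_equal(pick_bottom_consensus(low, 2)$chosen, "A")

  expect_error(pick_top_consensus(rt, 10), "exceeds")
})

test_that("consensus methods agree with brute-force enumeration on random tables", {
  withr::with_seed(2025, {
    for (i in 1:200) {
      scores <- matrix(round(runif(5 * 50), 3), 50, 5,
                       dimnames = list(NULL, c("m1", "m2", "m3", "m4", "m5")))
      task <- sample(c("MS2", "RT"), 1)
      t <- toy_table(scores, task)
      dir <- t$direction
      n <- sample(c(10, 25, 50), 1)
      top <- pick_top_consensus(t, n)
      expect_equal(top$votes, oracle_consensus(scores, dir, n, "top"))
      expect_equal(sum(top$votes), n)
      bot <- pick_bottom_consensus(t, n)
      expect_equal(bot$votes, oracle_consensus(scores, dir, n, "bottom"))
      expect_equal(sum(bot$votes), n)
    }
  })
})

test_that("every pick method attains the optimum of its own statistic", {
  withr::with_seed(303, {
    for (i in 1:50) {
      scores <- matrix(runif(5 * 200), 200, 5,
                       dimnames = list(NULL, paste0("m", 1:5)))
      task <- sample(c("MS2", "RT"), 1)
      t <- toy_table(scores, task)
      med <- pick_median(t)
      opt <- if (t$direction == "higher") max(med$per_model_statistic)
             else min(med$per_model_statistic)
      expect_equal(unname(med$per_model_statistic[med$chosen]), opt)
      top <- pick_top_consensus(t, 10)
      expect_equal(unname(top$votes[top$chosen]), max(top$votes))
      if (task == "RT") {
        r <- pick_rmse(t)
        expect_equal(unname(r$per_model_statistic[r$chosen]),
                     min(sqrt(colMeans(scores^2))))
      }
    }
  })
})

test_that("RMSE selection computes the stated arithmetic and rejects MS2", {
  t <- toy_table(cbind(A = c(0.5, 0.5), B = c(1, 0)), "RT")
  r <- pick_rmse(t)
  expect_equal(unname(r$per_model_statistic), c(0.5, sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(r$chosen, "A")
  tie <- toy_table(cbind(B = c(1, 1, 1, 1), A = c(0, 0, 0, 2)), "RT")
  expect_equal(unname(pick_rmse(tie)$per_model_statistic[c("A", "B")]),
               c(1, 1))
  expect_equal(pick_rmse(tie)$chosen, "A")
  expect_error(pick_rmse(toy_table(cbind(A = 1, B = 2), "MS2")), "RT")
  single <- score_table("p1", matrix(2, 1, 1, dimnames = list(NULL, "only")),
                        "RT")
  expect_equal(pick_rmse(single)$chosen, "only")
})

test_that("score tables drop PSMs unsupported by any model", {
  w <- tiny_world(seed = 31)
  sim <- simulate_dataset(w, 60, seed = 11)
  psms <- select_top_psms(list(sim$pin), 60)
  lens <- vapply(psms, function(r)
    nchar(pinboost:::pin_peptide_core(r$peptide)), integer(1))
  cap <- sort(unique(lens))[length(unique(lens)) - 1]
  backends <- list(
    ms2_a = synthetic_backend(w, "ms2_a"),
    ms2_d = synthetic_backend(w, "ms2_d", max_length = cap))
  t <- build_score_table(psms, sim$spectra, backends, task = "MS2",
                         nce = c(ms2_a = 27, ms2_d = 27))
  expect_equal(nrow(t$scores), sum(lens <= cap))
  expect_false(anyNA(t$scores))

  # a model supporting nothing is an error naming it
  bad <- list(ms2_a = synthetic_backend(w, "ms2_a"),
              tiny = synthetic_backend(w, "ms2_b", min_length = 1,
                                       max_length = 4))
  expect_error(build_score_table(psms, sim$spectra, bad, task = "MS2",
                                 nce = c(ms2_a = 27, tiny = 27)), "tiny")
})

test_that("noise ordering of synthetic MS2 models shows up in the medians", {
  w <- tiny_world(seed = 32)
  sim <- simulate_dataset(w, 150, seed = 12)
  psms <- select_top_psms(list(sim$pin), 100)
  backends <- sapply(c("ms2_a", "ms2_d"), function(m)
    synthetic_backend(w, m), simplify = FALSE)
  t <- build_score_table(psms, sim$spectra, backends, task = "MS2",
                         nce = c(ms2_a = 27, ms2_d = 27))
  med <- apply(t$scores, 2, median)
  expect_gt(med[["ms2_a"]], med[["ms2_d"]])
  expect_equal(pick_median(t)$chosen, "ms2_a")
})

test_that("heavy-tail RT model splits the median and top-consensus verdicts", {
  w <- tiny_world(seed = 33)
  sim <- simulate_dataset(w, 400, seed = 13)
  psms <- select_top_psms(list(sim$pin), 400)
  backends <- list(rt_shift = synthetic_backend(w, "rt_shift"),
                   rt_heavy = synthetic_backend(w, "rt_heavy"))
  t <- build_score_table(psms, sim$spectra, backends, task = "RT")
  med <- pick_median(t)
  top <- pick_top_consensus(t, 10)
  expect_equal(med$chosen, "rt_heavy")   # lower median deviation
  expect_equal(top$chosen, "rt_shift")   # lighter tail wins the top ranks
  # and the empirically better model is the light-tailed one
  out <- sim$truth$outcomes
  rt_out <- out[out$model %in% c("rt_shift", "rt_heavy"), ]
  expect_equal(rt_out$model[which.max(rt_out$mean_peptides)], "rt_shift")
})

test_that("select_models applies median for MS2 and top-consensus-10 for RT", {
  w <- tiny_world(seed = 34)
  sim <- simulate_dataset(w, 300, seed = 14)
  psms <- select_top_psms(list(sim$pin), 300)
  ms2_b <- sapply(c("ms2_a", "ms2_c"), function(m)
    synthetic_backend(w, m), simplify = FALSE)
  rt_b <- sapply(c("rt_shift", "rt_heavy"), function(m)
    synthetic_backend(w, m), simplify = FALSE)
  ms2_t <- build_score_table(psms, sim$spectra, ms2_b, task = "MS2",
                             nce = c(ms2_a = 27, ms2_c = 27))
  rt_t <- build_score_table(psms, sim$spectra, rt_b, task = "RT")
  sel <- select_models(ms2_t, rt_t)
  expect_equal(sel$ms2, pick_median(ms2_t)$chosen)
  expect_equal(sel$rt, pick_top_consensus(rt_t, 10)$chosen)
  expect_equal(sel$ms2_criterion, "median")
  expect_equal(sel$rt_criterion, "top_consensus_10")
  expect_named(sel$reports, c("MS2", "RT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(sel$reports, path)
  rep <- read.delim(path)
  expect_true(all(c("median", "rmse") %in% rep$method))
  expect_equal(sum(rep$chosen[rep$task == "MS2" & rep$method == "median"]), 1)
})

test_that("heuristic summary score equals the stated squared-ratio average", {
  outcomes <- data.frame(
    dataset = rep(c("d1", "d2"), each = 2),
    model = rep(c("A", "B"), 2),
    mean_peptides = c(1000, 900, 800, 1000))
  expect_equal(heuristic_summary_score(c(d1 = "A", d2 = "B"), outcomes), 1.0)
  expect_equal(heuristic_summary_score(c(d1 = "A", d2 = "A"), outcomes),
               (1 + 0.64) / 2)
  expect_equal(heuristic_summary_score(c(d1 = "B", d2 = "B"), outcomes),
               (0.81 + 1) / 2)
  # ratios 1.0 and 0.9 -> 0.905
  o2 <- data.frame(dataset = rep(c("d1", "d2"), each = 2),
                   model = rep(c("A", "B"), 2),
                   mean_peptides = c(100, 90, 90, 100))
  expect_equal(heuristic_summary_score(c(d1 = "A", d2 = "A"), o2), 0.905)
  # single dataset: r squared
  expect_equal(heuristic_summary_score(
    c(d1 = "B"), o2[o2$dataset == "d1", ]), 0.81)
  expect_error(heuristic_summary_score(c(d3 = "A"), o2), "d3")
})

test_that("position classification follows the gray/red/white interval rule", {
  outcomes <- data.frame(model = c("best", "close", "bad"),
                         mean_peptides = c(1000, 995, 900),
                         sd = c(10, 10, 10))
  # best model wins every position -> all gray
  t_gray <- toy_table(cbind(best = c(0.9, 0.8), close = c(0.5, 0.4),
                            bad = c(0.3, 0.2)), "MS2")
  expect_equal(classify_positions(t_gray, outcomes, "best"),
               c("gray", "gray"))
  # positions won by a clearly worse model are red; overlapping
  # intervals are white
  t_mix <- toy_table(cbind(best = c(0.5, 0.9), close = c(0.95, 0.1),
                           bad = c(0.97, 0.2)), "MS2")
  labs <- classify_positions(t_mix, outcomes, "best")
  # ascending sort: position 1 holds each model's smaller score
  # pos1: best 0.5 vs close 0.1 vs bad 0.2 -> best wins -> gray
  # pos2: bad 0.97 wins -> red (900 + 10 < 1000 - 10)
  expect_equal(labs, c("gray", "red"))
  t_white <- toy_table(cbind(best = c(0.5), close = c(0.9), bad = c(0.1)),
                       "MS2")
  expect_equal(classify_positions(t_white, outcomes, "best"), "white")
})
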