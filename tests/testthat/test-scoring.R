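test_that("partial score matches its closed form at the landmark points", {
  # l=10, u=20, s=1: Delta_l = 1*10*10/30 = 10/3
  expect_equal(partial_score(15, 10, 20, 1), 1)
  expect_equal(partial_score(10, 10, 20, 1), 1)
  expect_equal(partial_score(20, 10, 20, 1), 1)
  expect_equal(partial_score(10 - 10 / 3, 10, 20, 1), 0)
  expect_equal(partial_score(10 - 10 / 6, 10, 20, 1), 0.5)  # margin midpoint
  # upper margin: Delta_u = 1*20*10/30 = 20/3
  expect_equal(partial_score(20 + 20 / 3, 10, 20, 1), 0, tolerance = 1e-12)
  expect_equal(partial_score(20 + 10 / 3, 10, 20, 1), 0.5)
  expect_equal(partial_score(100, 10, 20, 1), 0)
})

test_that("s = 0 reduces the partial score to a hard interval test", {
  xs <- seq(0, 40, by = 0.25)
  expect_equal(partial_score(xs, 10, 20, 0), as.numeric(xs >= 10 & xs <= 20))
})

test_that("partial score is continuous and monotone on each side", {
  set.seed(31)
  for (i in 1:20) {
    l <- runif(1, 0, 50)
    u <- l + runif(1, 0.5, 50)
    s <- runif(1, 0.05, 2)
    m <- netquant:::score_margins(l, u, s)
    span <- c(l - m$dl - 1, u + m$du + 1)
    for (h in c(1e-3, 1e-4)) {
      xs <- seq(span[1], span[2], by = h * diff(span))
      sc <- partial_score(xs, l, u, s)
      expect_true(all(sc >= 0 & sc <= 1))
      max_slope <- pi / (2 * min(m$dl, m$du)) * diff(span)
      expect_lt(max(abs(diff(sc))), 1.5 * max_slope * h)
      left <- xs <= l
      expect_true(all(diff(sc[left]) >= -1e-12))
      right <- xs >= u
      expect_true(all(diff(sc[right]) <= 1e-12))
    }
  }
})

test_that("margins are relative: rescaling l, u and x leaves the score unchanged", {
  set.seed(32)
  for (i in 1:50) {
    l <- runif(1, 0.1, 30); u <- l + runif(1, 0.1, 30)
    s <- runif(1, 0, 2)
    x <- runif(1, 0, 2 * u)
    k <- runif(1, 0.01, 100)
    expect_equal(partial_score(k * x, k * l, k * u, s),
                 partial_score(x, l, u, s), tolerance = 1e-9)
  }
})

test_that("degenerate and open-ended ranges behave as documented", {
  # zero lower bound: hard lower edge
  expect_equal(partial_score(-0.001, 0, 10, 1), 0)
  expect_equal(partial_score(0, 0, 10, 1), 1)
  # point interval: hard equality
  expect_equal(partial_score(5, 5, 5, 1), 1)
  expect_equal(partial_score(5.0001, 5, 5, 1), 0)
  # infinite upper bound: no upper ramp, soft lower edge of width s*l
  expect_equal(partial_score(1e9, 10, Inf, 1), 1)
  expect_equal(partial_score(10 - 5, 10, Inf, 0.5), 0)
  expect_equal(partial_score(10 - 2.5, 10, Inf, 0.5), 0.5)
  # negative-valued interval (mean_log): margins use magnitudes, stay >= 0
  sc <- partial_score(seq(-80, 0, by = 0.5), -60, -20, 0.5)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(partial_score(-40, -60, -20, 0.5), 1)
  expect_error(partial_score(1, 5, 2, 1), "configuration")
})

test_that("class score is the product of partial scores, 1 iff all in range", {
  cd <- class_definition("PMN", list(area = c(10, 20), mean_total = c(100, 200)))
  fv <- list(area = 15, mean_total = 150, mean_extra = 5)
  expect_equal(class_score(fv, cd, s = 1), 1)
  # one feature on its margin midpoint -> product 0.5
  fv$area <- 10 - 10 / 6
  expect_equal(class_score(fv, cd, s = 1), 0.5)
  # any zero partial score annihilates
  fv$mean_total <- 1e6
  expect_equal(class_score(fv, cd, s = 1), 0)
  expect_error(class_score(list(area = 1), cd, 1), "unknown feature")
  expect_true(class_score(list(area = 12, mean_total = 120), cd, 0.5) <=
                partial_score(12, 10, 20, 0.5))
})

test_that("the decision rule assigns only unique high scorers", {
  expect_equal(decide_label(c(PMN = 0.9, RND = 0.1, RUP = 0))$label, "PMN")
  d <- decide_label(c(PMN = 0.9, RND = 0.5))
  expect_equal(d$label, "UNKNOWN_INTRACELLULAR")
  expect_equal(d$ambiguity_reason, "multiple_high_scores")
  d <- decide_label(c(PMN = 0.6, RND = 0.2))
  expect_equal(d$ambiguity_reason, "no_high_score")
  # closed comparisons: competitor exactly at the rejection threshold passes
  expect_equal(decide_label(c(A = 0.8, B = 0.4))$label, "A")
  # two high scorers are ambiguous
  expect_equal(decide_label(c(A = 0.9, B = 0.85))$ambiguity_reason,
               "multiple_high_scores")
})

test_that("classify never assigns a label scoring below the assignment threshold", {
  set.seed(33)
  classes <- list(
    class_definition("A", list(area = c(10, 20))),
    class_definition("B", list(area = c(30, 40))),
    class_definition("C", list(mean_total = c(5, 9)))
  )
  feats <- tibble::tibble(area = runif(200, 0, 50),
                          mean_total = runif(200, 0, 15))
  out <- classify_features(feats, classes, s = 0.8)
  assigned <- out$label != "UNKNOWN_INTRACELLULAR"
  expect_true(all(out$score[assigned] >= 0.8))
  expect_true(all(out$ambiguity_reason[assigned] == "none"))
  # full score table is always present and bounded
  expect_true(all(out$score_A >= 0 & out$score_A <= 1))

  # hard-threshold limit: at s = 0, assignment agrees with exact membership
  out0 <- classify_features(feats, classes, s = 0)
  members <- cbind(feats$area >= 10 & feats$area <= 20,
                   feats$area >= 30 & feats$area <= 40,
                   feats$mean_total >= 5 & feats$mean_total <= 9)
  expected <- apply(members, 1L, function(m) {
    if (sum(m) == 1) c("A", "B", "C")[m] else "UNKNOWN_INTRACELLULAR"
  })
  expect_equal(out0$label, expected)
})

test_that("configurations round-trip through YAML with infinity sentinels", {
  cfg <- preset_config("mixed_coculture")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$classes$RUP$mean_log, cfg$classes$RUP$mean_log)
  expect_equal(cfg2$stage1$net_std_range, c(150, Inf))
  expect_equal(cfg2$s, cfg$s)
  expect_equal(cfg2$segmentation$total_dna$threshold,
               cfg$segmentation$total_dna$threshold)
  # plain "inf" strings are accepted too
  txt <- c("s: 0.3", "classes:", "  NETish:", "    area: [100, inf]")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(txt, p2)
  cfg3 <- read_config(p2)
  expect_equal(cfg3$classes$NETish$area, c(100, Inf))
})
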