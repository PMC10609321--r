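grouped_df <- function(values_by_group) {
  tibble::tibble(
    line = rep(names(values_by_group), lengths(values_by_group)),
    y = unlist(values_by_group, use.names = FALSE)
  )
}

test_that("iqr trimming removes a gross outlier and leaves clean data alone", {
  d <- grouped_df(list(A = c(1, 2, 2, 3, 2, 2, 50)))
  out <- trim_outliers(d, y, line, rule = "iqr", k = 1.5)
  expect_equal(out$y, c(1, 2, 2, 3, 2, 2))
  expect_equal(attr(out, "removed")$y, 50)
  clean <- grouped_df(list(A = c(4, 5, 5, 6, 5)))
  expect_equal(trim_outliers(clean, y, line)$y, clean$y)
  tiny <- grouped_df(list(A = c(1, 2, 3)))
  expect_warning(trim_outliers(tiny, y, line), "fewer than 4")
})

test_that("zscore trimming removes >= 90% of planted shift outliers", {
  set.seed(31)
  n <- 500
  clean <- rnorm(n, 100, 5)
  planted <- sample(n, 25) # 5% contamination
  x <- clean
  x[planted] <- x[planted] + sample(c(-1, 1), 25, TRUE) * 10 * 5
  d <- grouped_df(list(A = x))
  out <- trim_outliers(d, y, line, rule = "zscore", k = 3)
  removed_idx <- which(!x %in% out$y)
  expect_gte(mean(planted %in% removed_idx), 0.90)
  expect_lte(length(removed_idx), 40) # few false removals
})

test_that("one-way ANOVA: identical groups give F = 0; two groups match t^2", {
  d0 <- grouped_df(list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4)))
  a0 <- anova_oneway(d0, y, line)
  expect_equal(a0$statistic, 0)
  expect_equal(a0$p.value, 1)

  set.seed(8)
  d2 <- grouped_df(list(A = rnorm(12), B = rnorm(15, 0.8)))
  a2 <- anova_oneway(d2, y, line)
  tt <- t.test(y ~ line, data = d2, var.equal = TRUE)
  expect_equal(a2$statistic, unname(tt$statistic)^2)
  expect_equal(a2$p.value, tt$p.value)

  expect_error(anova_oneway(grouped_df(list(A = c(1, 1), B = c(1, 1))),
                            y, line), "zero variance")
  expect_error(anova_oneway(grouped_df(list(A = 1:3)), y, line),
               "at least 2 groups")
})

test_that("ANOVA type-I error is 0.05 +/- 0.02 under a null simulation", {
  set.seed(404)
  reps <- 1000
  hits <- 0
  for (r in seq_len(reps)) {
    d <- grouped_df(list(A = rnorm(20), B = rnorm(20), C = rnorm(20),
                         D = rnorm(20), E = rnorm(20)))
    if (anova_oneway(d, y, line)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("pairwise t tests match the hand-computed pooled formula", {
  d <- grouped_df(list(A = c(1, 2, 3), B = c(2, 4, 6), C = c(10, 11, 12)))
  pt <- pairwise_t(d, y, line)
  expect_equal(nrow(pt), 3)
  # hand computation for the A-B pair
  xa <- c(1, 2, 3); xb <- c(2, 4, 6)
  sp2 <- (2 * var(xa) + 2 * var(xb)) / 4
  t_hand <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  ab <- pt[pt$group1 == "A" & pt$group2 == "B", ]
  expect_equal(ab$statistic, t_hand)
  expect_equal(ab$p.value, p_hand)
  # antisymmetry of the estimate under group order
  expect_equal(ab$estimate, -(mean(xb) - mean(xa)))
  # identical groups: p in the no-signal region
  same <- grouped_df(list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4)))
  expect_equal(pairwise_t(same, y, line)$p.value, 1)
})

test_that("tukey_kramer reduces to classical Tukey HSD for equal n", {
  set.seed(21)
  d <- grouped_df(list(A = rnorm(12, 10), B = rnorm(12, 10.6),
                       C = rnorm(12, 12), D = rnorm(12, 9.4)))
  tk <- tukey_kramer(d, y, line)
  ref <- TukeyHSD(aov(y ~ line, data = d))$line
  key <- paste(tk$pairs$group2, tk$pairs$group1, sep = "-")
  key2 <- paste(tk$pairs$group1, tk$pairs$group2, sep = "-")
  pos <- ifelse(is.na(match(key, rownames(ref))),
                match(key2, rownames(ref)), match(key, rownames(ref)))
  ref_p <- ref[, "p adj"][pos]
  expect_equal(tk$pairs$p.adj, unname(ref_p), tolerance = 1e-8)
})

test_that("tukey_kramer handles unequal n and is invariant to relabeling and shifts", {
  set.seed(22)
  gl <- list(A = rnorm(9, 5), B = rnorm(14, 5.5), C = rnorm(23, 7))
  tk <- tukey_kramer(grouped_df(gl), y, line)
  # Kramer form of the standard error
  ab <- tk$pairs[tk$pairs$group1 == "A" & tk$pairs$group2 == "B", ]
  expect_equal(ab$se, sqrt(tk$mse / 2 * (1 / 9 + 1 / 14)))
  expect_equal(tk$df_error, 9 + 14 + 23 - 3)

  relab <- setNames(gl, c("Zeta", "Eta", "Iota"))
  tk2 <- tukey_kramer(grouped_df(relab), y, line)
  expect_equal(sort(tk2$pairs$p.adj), sort(tk$pairs$p.adj))

  shifted <- lapply(gl, `+`, 100)
  tk3 <- tukey_kramer(grouped_df(shifted), y, line)
  expect_equal(tk3$pairs$p.adj, tk$pairs$p.adj)
  expect_equal(tk3$pairs$q, tk$pairs$q)

  expect_error(tukey_kramer(grouped_df(list(A = 1:5, B = 3)), y, line),
               "fewer than 2")
})

test_that("equal means yield no significant pairs and a single letter", {
  d <- grouped_df(list(A = c(5, 6, 7, 8), B = c(5, 6, 7, 8),
                       C = c(5, 6, 7, 8)))
  tk <- tukey_kramer(d, y, line)
  expect_false(any(tk$pairs$significant))
  expect_true(all(tk$letters$letters == "A"))
})

test_that("a 1-sd-shifted group separates from all others in >= 95% of reps", {
  set.seed(77)
  reps <- 100
  separated <- 0
  for (r in seq_len(reps)) {
    gl <- c(lapply(setNames(1:4, c("A", "B", "C", "D")),
                   function(i) rnorm(100, 10, 2)),
            list(E = rnorm(100, 12, 2))) # +1 sd shift
    tk <- tukey_kramer(grouped_df(gl), y, line)
    e_pairs <- tk$pairs[tk$pairs$group1 == "E" | tk$pairs$group2 == "E", ]
    if (all(e_pairs$significant)) separated <- separated + 1
  }
  expect_gte(separated / reps, 0.95)
})

test_that("connecting letters satisfy the sharing iff non-significance contract", {
  all_pairs <- function(groups) {
    idx <- utils::combn(length(groups), 2)
    tibble::tibble(group1 = groups[idx[1, ]], group2 = groups[idx[2, ]])
  }
  # all non-significant: everyone shares "A"; all significant: all distinct
  g <- c("L1", "L2", "L3", "L4")
  p <- all_pairs(g)
  p$significant <- FALSE
  expect_true(all(connecting_letters(p)$letters == "A"))
  p$significant <- TRUE
  expect_equal(sort(connecting_letters(p)$letters), c("A", "B", "C", "D"))
  # missing pair errors
  expect_error(connecting_letters(p[-1, ]), "incomplete")
})

test_that("letters match the brute-force clique oracle for every pattern on 4 groups", {
  groups <- paste0("G", 1:4)
  idx <- utils::combn(4, 2)
  n_pairs <- ncol(idx)
  for (pattern in 0:(2^n_pairs - 1)) {
    sig <- as.logical(bitwAnd(pattern, 2^(seq_len(n_pairs) - 1)))
    pairs <- tibble::tibble(group1 = groups[idx[1, ]],
                            group2 = groups[idx[2, ]],
                            significant = sig)
    lets <- connecting_letters(pairs)
    share <- function(a, b) {
      la <- strsplit(lets$letters[lets$group == a], "")[[1]]
      lb <- strsplit(lets$letters[lets$group == b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    # contract: share a letter iff the pair is not significant
    for (j in seq_len(n_pairs)) {
      expect_identical(share(groups[idx[1, j]], groups[idx[2, j]]),
                       !sig[j])
    }
    # every letter class is contained in some maximal non-significant clique
    sig_lookup <- function(a, b) {
      i <- which((pairs$group1 == a & pairs$group2 == b) |
                 (pairs$group1 == b & pairs$group2 == a))
      pairs$significant[i]
    }
    cliques <- maximal_nonsig_cliques(groups, sig_lookup)
    all_letters <- unique(unlist(strsplit(lets$letters, "")))
    for (L in all_letters) {
      members <- lets$group[grepl(L, lets$letters, fixed = TRUE)]
      expect_true(any(vapply(cliques, function(cl) all(members %in% cl),
                             logical(1))))
    }
    expect_lte(length(all_letters), length(cliques))
  }
})

test_that("letter rows follow descending means like a report table", {
  set.seed(12)
  d <- grouped_df(list(Lo = rnorm(30, 5), Mid = rnorm(30, 20),
                       Hi = rnorm(30, 40)))
  tk <- tukey_kramer(d, y, line)
  expect_equal(tk$letters$group, c("Hi", "Mid", "Lo"))
  expect_true(all(diff(tk$letters$mean) < 0))
  # tidy/glance accessors
  expect_s3_class(tidy(tk), "tbl_df")
  expect_equal(glance(tk)$k, 3)
  expect_s3_class(autoplot(tk), "ggplot")
})

test_that("line_summary returns monotone quantiles per line", {
  set.seed(2)
  d <- grouped_df(list(A = rnorm(40, 10, 2), B = rnorm(25, 14, 3)))
  sm <- line_summary(d, y, line)
  expect_equal(nrow(sm), 2)
  qs <- as.matrix(sm[, c("min", "q25", "median", "q75", "max")])
  expect_true(all(apply(qs, 1, function(r) all(diff(r) >= 0))))
  expect_equal(sm$n, c(25, 40)) # sorted by descending mean: B first
})

test_that("analyze_metric bundles the full battery", {
  set.seed(9)
  d <- grouped_df(list(A = rnorm(30, 10), B = rnorm(30, 10.2),
                       C = rnorm(30, 15)))
  res <- analyze_metric(d, y, line)
  expect_named(res, c("summary", "anova", "pairwise_t", "hsd", "removed"))
  expect_s3_class(res$hsd, "tukey_kramer")
  expect_lt(res$anova$p.value, 0.01)
  lc <- res$hsd$letters
  expect_false(any(strsplit(lc$letters[lc$group == "C"], "")[[1]] %in%
                   strsplit(lc$letters[lc$group == "A"], "")[[1]]))
})
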