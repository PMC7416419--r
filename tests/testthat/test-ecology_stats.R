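test_that("Simpson's index of diversity covers degenerate and even rows", {
  tab <- tibble::tibble(sample_id = c("mono", "even4"),
                        A = c(100, 25), B = c(0, 25), C = c(0, 25),
                        D = c(0, 25))
  out <- simpson_diversity(tab)
  expect_equal(out$simpson, c(0, 0.75))
  expect_error(simpson_diversity(tibble::tibble(sample_id = "x", A = 50)),
               "sum to 100")

  # bounds 0 <= D <= 1 - 1/K, and dominance strictly decreases diversity
  withr::local_seed(13)
  rt <- random_abundance_table(20, 6)
  d <- simpson_diversity(rt)$simpson
  expect_true(all(d >= 0 & d <= 1 - 1 / 6 + 1e-12))
  # pushing share into an already-dominant taxon strictly lowers diversity
  as_row <- function(v) {
    out <- tibble::as_tibble(as.data.frame(t(v)))
    dplyr::mutate(out, sample_id = "s", .before = 1)
  }
  start <- c(40, 30, 20, 10)
  prev <- simpson_diversity(as_row(start))$simpson
  for (boost in c(10, 25, 40)) {
    dominated <- start * (100 - boost) / 100
    dominated[1] <- dominated[1] + boost
    cur <- simpson_diversity(as_row(dominated))$simpson
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("Bray-Curtis similarity has the expected fixed points", {
  tab <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                        t1 = c(100, 0, 100, 50), t2 = c(0, 100, 0, 50))
  s <- bray_curtis(tab)
  expect_equal(unclass(s)["a", "b"], 0)      # disjoint
  expect_equal(unclass(s)["a", "c"], 100)    # identical
  expect_equal(unclass(s)["a", "a"], 100)    # self
  # hand formula for (100,0) vs (50,50) on sqrt scale
  expect_equal(unclass(s)["a", "d"], oracle_bray_pair(c(100, 0), c(50, 50)))
  # symmetry and bounds on random tables
  withr::local_seed(19)
  rt <- random_abundance_table(8, 5)
  m <- unclass(bray_curtis(rt))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 100 + 1e-9))
})

test_that("SIMPER terms sum to the pairwise Bray-Curtis values", {
  withr::local_seed(23)
  worst <- 0
  for (rep in 1:10) {
    tab <- random_abundance_table(6, 5)
    groups <- setNames(rep(c("g1", "g2"), each = 3), tab$sample_id)
    sm <- simper_contrib(tab, groups)
    s <- unclass(bray_curtis(tab))
    # within-group: mean contribution sums equal mean pairwise similarity
    for (g in c("g1", "g2")) {
      ids <- names(groups)[groups == g]
      pairs <- utils::combn(ids, 2)
      mean_sim <- mean(apply(pairs, 2, function(p) s[p[1], p[2]]))
      tot <- sum(sm$within$contribution[sm$within$group == g])
      worst <- max(worst, abs(tot - mean_sim))
    }
    # between-group: contributions sum to mean pairwise dissimilarity
    ids1 <- names(groups)[groups == "g1"]; ids2 <- names(groups)[groups == "g2"]
    mean_dis <- mean(100 - s[ids1, ids2])
    worst <- max(worst, abs(sum(sm$between$contribution) - mean_dis))
  }
  expect_lt(worst, 1e-9)
})

test_that("SIMPER ranks the group-discriminating taxa on a constructed fixture", {
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    dom1 = c(90, 85, 88, 5, 4, 6),
    dom2 = c(4, 6, 5, 86, 88, 85),
    shared = c(6, 9, 7, 9, 8, 9))
  groups <- setNames(rep(c("summer", "winter"), each = 3), tab$sample_id)
  sm <- simper_contrib(tab, groups)
  top2 <- sm$between$taxon[sm$between$rank <= 2]
  expect_setequal(top2, c("dom1", "dom2"))

  # identical groups: zero dissimilarity everywhere
  same <- tibble::tibble(sample_id = paste0("s", 1:4),
                         A = 60, B = 40)
  sm0 <- simper_contrib(same, setNames(rep(c("x", "y"), 2), same$sample_id))
  expect_equal(sum(sm0$between$contribution), 0)
  expect_equal(sm0$between$mean_dissimilarity, rep(0, nrow(sm0$between)))

  # undersized group triggers a warning and is skipped for similarity
  expect_warning(
    simper_contrib(tab, setNames(c("a", rep("b", 5)), tab$sample_id)),
    "< 2 samples")
})

test_that("SIMPER between-group averages agree with vegan::simper", {
  withr::local_seed(29)
  tab <- random_abundance_table(8, 6)
  groups <- setNames(rep(c("g1", "g2"), each = 4), tab$sample_id)
  sm <- simper_contrib(tab, groups)
  m <- sqrt(as.matrix(tab[, -1]))
  rownames(m) <- tab$sample_id
  vg <- summary(vegan::simper(m, groups[tab$sample_id],
                              permutations = 0))$g1_g2
  ours <- sm$between$contribution[match(rownames(vg), sm$between$taxon)]
  # vegan reports average contributions on the 0-1 scale
  expect_equal(ours, vg$average * 100, tolerance = 1e-6)
})

test_that("a planted single gradient is fully captured by dbRDA axis 1", {
  withr::local_seed(37)
  n <- 24
  grad <- seq(-1.5, 1.5, length.out = n)
  p <- 20 + 60 * stats::plogis(2 * grad)  # composition driven by gradient
  tab <- tibble::tibble(sample_id = paste0("s", 1:n),
                        A = p, B = 100 - p)
  env <- tibble::tibble(sample_id = tab$sample_id, driver = grad,
                        noise = rnorm(n))
  env_n <- env_normalize(env, variables = c("driver", "noise"))
  fit <- dbrda_fit(bray_curtis(tab), env_n, selection = "forward")
  expect_equal(fit$selected[1], "driver")
  expect_gt(fit$axes$pct_fitted[1], 99)
  # axis 1 carries essentially all the fitted variation on the total scale
  expect_equal(fit$axes$pct_total[1], sum(fit$axes$pct_total),
               tolerance = 0.01)
  planted_total <- sum(fit$axes$pct_total)
  expect_gt(planted_total, 60)

  # permuting the env labels collapses the fit
  envp <- env_n
  envp$driver <- sample(envp$driver)
  fitp <- dbrda_fit(bray_curtis(tab),
                    envp[, c("sample_id", "driver")], selection = "all")
  expect_lt(sum(fitp$axes$pct_total), planted_total / 4)
})

test_that("pure-noise environment explains almost nothing at n = 60", {
  withr::local_seed(43)
  n <- 60
  tab <- random_abundance_table(n, 8)
  env <- tibble::tibble(sample_id = tab$sample_id,
                        v1 = rnorm(n), v2 = rnorm(n))
  fit <- dbrda_fit(bray_curtis(tab),
                   env_normalize(env, c("v1", "v2")), selection = "all")
  expect_lt(sum(fit$axes$pct_total), 5)
})

test_that("collinear environmental columns are rejected by name", {
  n <- 10
  env <- tibble::tibble(sample_id = paste0("s", 1:n),
                        a = 1:n, b = 2 * (1:n))
  tab <- random_abundance_table(n, 4)
  expect_error(dbrda_fit(bray_curtis(tab), env_normalize(env, c("a", "b"))),
               "collinear.*a.*b")
})

test_that("environmental normalization yields mean 0, sd 1 and drops incomplete rows", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:5),
                         depth_m = c(0, 5, 12, 14, NA),
                         salinity_pct = c(1.6, 1.7, 2.5, 4, 4.2))
  expect_message(out <- env_normalize(meta), "dropping 1")
  expect_equal(nrow(out), 4)
  expect_equal(mean(out$depth_m), 0)
  expect_equal(sd(out$salinity_pct), 1)
})

test_that("Pearson and regression agree on their shared identities", {
  x <- c(1, 3, 2, 5, 4, 7)
  y <- 2 * x
  expect_equal(pearson_cor(x, y)$r, 1)
  reg <- suppressWarnings(anova_regression(x, y))  # exact fit
  expect_equal(reg$slope, 2)
  expect_error(pearson_cor(rep(1, 5), x[1:5]), "constant")
  expect_error(anova_regression(rep(1, 5), x[1:5]), "constant")

  withr::local_seed(47)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(pearson_cor(x, y)$r^2, anova_regression(x, y)$r_squared,
               tolerance = 1e-12)
})
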