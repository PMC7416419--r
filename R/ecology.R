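#' Simpson's index of diversity for one metagenome
#'
#' Computes 1 - sum(p_i^2) over all columns of the abundance row (including
#' the Other and unassigned columns by default; restrict the input columns
#' to change scope). Rows must sum to 100.
#'
#' @param table Abundance table (`sample_id` plus percent columns).
#' @return Tibble `sample_id`, `simpson` with values in [0, 1].
#' @export
simpson_diversity <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "sample_id")])
  sums <- rowSums(m)
  if (any(abs(sums - 100) > 1e-6)) {
    abort("abundance rows must sum to 100")
  }
  p <- m / 100
  tibble::tibble(sample_id = table$sample_id,
                 simpson = 1 - rowSums(p^2))
}

#' Bray-Curtis resemblance matrix on transformed abundances
#'
#' Relative abundances are square-root transformed and pairwise Bray-Curtis
#' similarity (percent) computed:
#' \eqn{S_{jk} = 100 \cdot 2\sum_i \min(y_{ij}, y_{ik}) / \sum_i (y_{ij}+y_{ik})}.
#'
#' @param table Abundance table (`sample_id` plus percent columns).
#' @param transform `"sqrt"` (the standard choice) or `"none"`.
#' @return A `resemblance` object: similarity matrix (%) with sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(table, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  m <- as.matrix(table[, setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  y <- if (transform == "sqrt") sqrt(m) else m
  d <- as.matrix(vegan::vegdist(y, method = "bray"))
  s <- 100 * (1 - d)
  diag(s) <- 100
  structure(s, class = c("resemblance", "matrix"))
}

#' @export
print.resemblance <- function(x, ...) {
  cat("Bray-Curtis resemblance matrix (%):", nrow(x), "samples\n")
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x)))],
        digits = 4)
  invisible(x)
}

#' SIMPER: per-taxon contributions to similarity and dissimilarity
#'
#' Decomposes pairwise Bray-Curtis similarity/dissimilarity (on square-root
#' transformed abundances) into per-taxon terms. For a sample pair (j, k)
#' with transformed abundances y, taxon i contributes
#' \eqn{100 \cdot 2\min(y_{ij}, y_{ik}) / \sum_s (y_{sj}+y_{sk})} to their
#' similarity and \eqn{100 \cdot |y_{ij}-y_{ik}| / \sum_s (y_{sj}+y_{sk})}
#' to their dissimilarity; the terms sum exactly to the pair's Bray-Curtis
#' similarity/dissimilarity. Contributions are averaged over within-group
#' pairs (similarity) and between-group pairs (dissimilarity) and ranked.
#'
#' @param table Abundance table (`sample_id` plus percent columns).
#' @param groups Named character vector or tibble (`sample_id`, `group`)
#'   mapping samples to groups (e.g. seasons).
#' @return A `lake_simper` object: list with tibbles `within` (`group`,
#'   `taxon`, `contribution`, `rank`, plus group mean similarity) and
#'   `between` (`group_1`, `group_2`, `taxon`, `contribution`, `rank`).
#'   Groups with fewer than two samples are skipped with a warning.
#' @export
simper_contrib <- function(table, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  stopifnot(all(table$sample_id %in% names(groups)))
  g <- groups[table$sample_id]
  m <- as.matrix(table[, setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  y <- sqrt(m)
  taxa <- colnames(y)

  pair_terms <- function(j, k) {
    denom <- sum(y[j, ] + y[k, ])
    list(sim = 100 * 2 * pmin(y[j, ], y[k, ]) / denom,
         dis = 100 * abs(y[j, ] - y[k, ]) / denom)
  }

  gl <- unique(g)
  within <- list()
  for (grp in gl) {
    idx <- which(g == grp)
    if (length(idx) < 2) {
      warn(sprintf("group '%s' has < 2 samples; within-group similarity skipped", grp))
      next
    }
    acc <- matrix(0, nrow = 0, ncol = length(taxa))
    for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
      acc <- rbind(acc, pair_terms(idx[a], idx[b])$sim)
    }
    contr <- colMeans(acc)
    within[[grp]] <- tibble::tibble(
      group = grp, taxon = taxa, contribution = unname(contr),
      mean_similarity = sum(contr)) |>
      dplyr::arrange(dplyr::desc(.data$contribution)) |>
      dplyr::mutate(rank = dplyr::row_number())
  }

  between <- list()
  if (length(gl) >= 2) {
    for (a in seq_along(gl)) for (b in seq_len(a - 1)) {
      i1 <- which(g == gl[a]); i2 <- which(g == gl[b])
      acc <- matrix(0, nrow = 0, ncol = length(taxa))
      for (j in i1) for (k in i2) acc <- rbind(acc, pair_terms(j, k)$dis)
      contr <- colMeans(acc)
      between[[paste(gl[a], gl[b])]] <- tibble::tibble(
        group_1 = gl[b], group_2 = gl[a], taxon = taxa,
        contribution = unname(contr),
        mean_dissimilarity = sum(contr)) |>
        dplyr::arrange(dplyr::desc(.data$contribution)) |>
        dplyr::mutate(rank = dplyr::row_number())
    }
  }
  structure(list(within = dplyr::bind_rows(within),
                 between = dplyr::bind_rows(between)),
            class = "lake_simper")
}

#' @export
print.lake_simper <- function(x, ...) {
  cat("SIMPER decomposition\n")
  cat("Within-group similarity contributions (top rows):\n")
  print(head(x$within, 5))
  cat("Between-group dissimilarity contributions (top rows):\n")
  print(head(x$between, 5))
  invisible(x)
}

#' Z-score normalize environmental variables
#'
#' Samples with missing values in any used column are dropped (with a
#' message reporting the count), then each column is centred and scaled to
#' unit standard deviation.
#'
#' @param meta Tibble with `sample_id` and environmental columns.
#' @param variables Character vector of columns to use; default the five
#'   standard drivers present in `meta`.
#' @return Tibble `sample_id` plus normalized columns.
#' @export
env_normalize <- function(meta, variables = NULL) {
  std <- c("depth_m", "salinity_pct", "daylength_h", "sunlight_h",
           "air_temp_C")
  variables <- variables %||% intersect(std, names(meta))
  stopifnot(length(variables) > 0, all(variables %in% names(meta)))
  sub <- meta[, c("sample_id", variables)]
  keep <- stats::complete.cases(sub[, variables])
  if (any(!keep)) {
    inform(sprintf("dropping %d sample(s) with missing environmental values",
                   sum(!keep)))
    sub <- sub[keep, ]
  }
  for (v in variables) {
    sub[[v]] <- as.numeric(scale(sub[[v]]))
  }
  sub
}

#' Distance-based redundancy analysis of community composition
#'
#' Fits the Bray-Curtis dissimilarity structure (100 - similarity) to
#' normalized environmental variables via principal coordinates with a
#' Lingoes correction for negative eigenvalues, i.e. a distance-based
#' linear model. Reports per-axis percent of fitted and of total variation
#' and per-variable marginal (single-variable) adjusted R-squared. With
#' `selection = "forward"`, variables are added greedily while the adjusted
#' R-squared of the model improves; ties break by column order.
#'
#' @param resemblance A [bray_curtis()] matrix.
#' @param env Normalized environment tibble from [env_normalize()]; only
#'   samples present in both are used.
#' @param selection `"all"` (use every variable) or `"forward"`.
#' @return A `lake_dbrda` object with elements `scores` (tibble of sample
#'   axis scores), `axes` (tibble `axis`, `eigenvalue`, `pct_fitted`,
#'   `pct_total`), `marginal` (per-variable adjusted R2), `selected`
#'   (variables in selection order), `adj_r_squared`, and the underlying
#'   vegan fit as `fit`.
#' @export
dbrda_fit <- function(resemblance, env, selection = c("all", "forward")) {
  selection <- match.arg(selection)
  ids <- intersect(rownames(resemblance), env$sample_id)
  if (length(ids) < 3) abort("need at least 3 samples with environmental data")
  env <- env[match(ids, env$sample_id), ]
  vars <- setdiff(names(env), "sample_id")
  x <- as.data.frame(env[, vars])
  # collinearity guard: condition number of the predictor matrix
  kap <- kappa(as.matrix(x), exact = TRUE)
  if (!is.finite(kap) || kap > 1e6) {
    cm <- abs(stats::cor(x)); diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    abort(sprintf("collinear environmental columns: %s, %s",
                  vars[worst[1]], vars[worst[2]]))
  }
  d <- stats::as.dist(100 - unclass(resemblance)[ids, ids])

  fit_vars <- function(v) {
    fml <- stats::as.formula(paste("d ~", paste(v, collapse = " + ")))
    vegan::capscale(fml, data = x, add = "lingoes")
  }
  adj_r2 <- function(fit) vegan::RsquareAdj(fit)$adj.r.squared

  marginal <- tibble::tibble(
    variable = vars,
    adj_r_squared = vapply(vars, function(v) adj_r2(fit_vars(v)), numeric(1))
  )

  if (selection == "forward") {
    selected <- character(0)
    current <- -Inf
    remaining <- vars
    repeat {
      if (length(remaining) == 0) break
      cand <- vapply(remaining,
                     function(v) adj_r2(fit_vars(c(selected, v))), numeric(1))
      best <- which.max(cand)  # ties -> first in column order
      if (cand[best] <= current) break
      current <- cand[best]
      selected <- c(selected, remaining[best])
      remaining <- remaining[-best]
    }
    if (length(selected) == 0) selected <- vars[1]
  } else {
    selected <- vars
  }
  fit <- fit_vars(selected)

  eig <- fit$CCA$eig
  tot <- fit$tot.chi
  axes <- tibble::tibble(
    axis = seq_along(eig),
    eigenvalue = unname(eig),
    pct_fitted = unname(eig / sum(eig) * 100),
    pct_total = unname(eig / tot * 100)
  )
  sc <- vegan::scores(fit, display = "sites",
                      choices = seq_along(eig))
  scores <- tibble::as_tibble(as.data.frame(sc)) |>
    dplyr::mutate(sample_id = ids, .before = 1)
  structure(list(scores = scores, axes = axes, marginal = marginal,
                 selected = selected, adj_r_squared = adj_r2(fit),
                 fit = fit),
            class = "lake_dbrda")
}

#' @export
print.lake_dbrda <- function(x, ...) {
  cat("Distance-based RDA (", length(x$selected), "variable(s):",
      paste(x$selected, collapse = ", "), ")\n")
  cat(sprintf("Adjusted R-squared: %.3f\n", x$adj_r_squared))
  print(x$axes, n = 4)
  invisible(x)
}

#' Pearson correlation between two abundance series
#'
#' @param x,y Numeric vectors of equal length (>= 3, non-constant).
#' @return Tibble `r`, `p` (two-sided).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length series with at least 3 observations")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("constant series")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' Simple regression with ANOVA significance test
#'
#' Ordinary least squares of `y` on `x` with the regression F test.
#'
#' @param x,y Numeric vectors.
#' @return Tibble `slope`, `intercept`, `F`, `p`, `r_squared`.
#' @export
anova_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need equal-length series with at least 3 observations")
  }
  if (sd(x) == 0) abort("constant predictor")
  fit <- lm(y ~ x)
  a <- anova(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 F = a$`F value`[1], p = a$`Pr(>F)`[1],
                 r_squared = summary(fit)$r.squared)
}
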