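#' Cue-induced spectral shifts
#'
#' For every (subject, channel, cue type) key of a slope table, computes
#' `Shift_k = slope(post-cue-k) - slope(pre-cue)`. A steeper post-cue
#' spectrum (clockwise rotation, increased inhibition) therefore gives a
#' negative shift; a flatter one (counterclockwise, increased E:I ratio) a
#' positive shift. By default only the ERP-removed variant is used, since
#' phase-locked power inflates post-cue slope estimates.
#'
#' @param st a slope table from [fit_spectrumset()].
#' @param baseline label of the baseline window (default `"pre_cue"`).
#' @param variant spectrum variant to use (default `"erp_removed"`;
#'   ignored if the table has no `variant` column).
#' @return data.frame with columns subject, channel, cue_type, shift
#'   (`Shift1`, `Shift2`, ... in post-window order), window, value.
#' @export
#' @examples
#' st <- data.frame(subject = "s1", window = c("pre_cue", "post_cue_1"),
#'                  channel = "Cz", cue_type = "neutral",
#'                  variant = "erp_removed", slope = c(-1.0, -1.2))
#' compute_shifts(st)$value  # -0.2
compute_shifts <- function(st, baseline = "pre_cue",
                           variant = "erp_removed") {
  if ("variant" %in% names(st)) st <- st[st$variant == variant, , drop = FALSE]
  if (!nrow(st)) stop("no slope rows for variant '", variant, "'",
                      call. = FALSE)
  wins <- unique(st$window)
  if (!baseline %in% wins)
    stop("key error: baseline window '", baseline,
         "' absent from slope table", call. = FALSE)
  post <- sort(setdiff(wins, baseline))
  key <- c("subject", "channel", "cue_type")
  keep <- intersect(c(key, "age_group"), names(st))
  base <- st[st$window == baseline, c(keep, "slope")]
  names(base)[names(base) == "slope"] <- "baseline_slope"
  out <- lapply(seq_along(post), function(k) {
    pk <- st[st$window == post[k], c(keep, "slope")]
    m <- merge(pk, base, by = keep, all.x = TRUE)
    if (anyNA(m$baseline_slope)) {
      bad <- m[is.na(m$baseline_slope), key]
      stop("key error: missing baseline slope for ",
           paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "),
           call. = FALSE)
    }
    m$shift <- paste0("Shift", k)
    m$window <- post[k]
    m$value <- m$slope - m$baseline_slope
    m[c(keep, "shift", "window", "value")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average a channel-keyed table over electrode clusters
#'
#' Replaces the `channel` column by a `cluster` column holding the per-key
#' arithmetic mean across each cluster's member channels.
#'
#' @param tbl a slope or shift table with a `channel` column and a numeric
#'   `value` (or `slope`) column.
#' @param clusters named list mapping cluster label to channel vector.
#' @return the cluster-averaged table.
#' @export
cluster_average <- function(tbl, clusters) {
  if (!length(clusters)) stop("config error: no clusters given", call. = FALSE)
  valcol <- if ("value" %in% names(tbl)) "value" else "slope"
  chans <- unique(tbl$channel)
  out <- lapply(names(clusters), function(cl) {
    members <- clusters[[cl]]
    if (!length(members))
      stop("config error: cluster '", cl, "' is empty", call. = FALSE)
    miss <- setdiff(members, chans)
    if (length(miss))
      stop("key error: cluster '", cl, "' channel(s) not in table: ",
           paste(miss, collapse = ", "), call. = FALSE)
    sub <- tbl[tbl$channel %in% members, , drop = FALSE]
    by_cols <- setdiff(names(sub), c("channel", valcol))
    agg <- stats::aggregate(sub[[valcol]], by = sub[by_cols], FUN = mean)
    names(agg)[ncol(agg)] <- valcol
    agg$cluster <- cl
    agg
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("cluster", setdiff(names(out), c("cluster", valcol)), valcol)]
}

## ---- permutation mixed ANOVA ------------------------------------------

## Orthonormal between-cell contrast matrix for a within-effect term:
## Kronecker product of scaled Helmert contrasts for factors in the term
## and the uniform average for factors not in it. Columns are orthonormal,
## so projecting subject cell vectors onto them reproduces the classical
## split-plot sums of squares (up to a common scale that cancels in F and
## partial eta squared).
term_contrast <- function(within_levels, term) {
  mats <- lapply(names(within_levels), function(f) {
    m <- length(within_levels[[f]])
    if (f %in% term) {
      h <- stats::contr.helmert(m)
      sweep(h, 2, sqrt(colSums(h^2)), "/")
    } else {
      matrix(1 / m, nrow = m, ncol = 1)
    }
  })
  Reduce(`%x%`, rev(mats))   # cell order: first factor varies slowest
}

## F, dfs and partial eta^2 for projected scores Z (subjects x df_term)
## under a group assignment g (integer vector). Error stratum is the
## subject x term interaction within groups.
f_from_scores <- function(Z, g, df_term) {
  n <- nrow(Z)
  ng <- tabulate(g)
  k <- length(ng)
  zbar <- colMeans(Z)
  ss_term <- n * sum(zbar^2)
  gm <- rowsum(Z, g) / ng                    # group means, k x df
  ss_gterm <- sum(ng * rowSums(sweep(gm, 2, zbar)^2))
  ss_err <- sum(Z^2) - sum(ng * rowSums(gm^2))
  df_g <- (k - 1) * df_term
  df_err <- (n - k) * df_term
  list(term = c(F = (ss_term / df_term) / (ss_err / df_err),
                df1 = df_term, df2 = df_err,
                pes = ss_term / (ss_term + ss_err)),
       gterm = if (k > 1)
         c(F = (ss_gterm / df_g) / (ss_err / df_err),
           df1 = df_g, df2 = df_err,
           pes = ss_gterm / (ss_gterm + ss_err)))
}

#' Mixed ANOVA with sign-flip permutation p-values
#'
#' Classical split-plot (mixed) ANOVA for a balanced design with one
#' observation per subject and within-cell, an optional between-subject
#' factor, and any number of fully crossed within-subject factors. Observed
#' F statistics use the standard sums-of-squares decomposition with subject
#' as random factor; each effect's error stratum is its subject-by-effect
#' interaction (between effect: subjects within groups). p-values are
#' permutation-based: per iteration the subject-level effect contrasts are
#' sign-flipped for a random half of the subjects (within effects), or the
#' group labels are permuted (effects involving the between factor), and
#' `p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1)`. Effect size is partial
#' eta squared `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data long-format data.frame.
#' @param dv name of the numeric response column.
#' @param subject name of the subject-id column.
#' @param within character vector of within-subject factor column names.
#' @param between optional name of the between-subject factor column.
#' @param n_perm number of permutations (default 10,000; < 100 warns).
#' @param seed integer RNG seed for the permutation draws.
#' @param flip sign-flip scheme for within effects: `"independent"`
#'   (default; every subject's contrast flips with probability 1/2, a
#'   transformation group, exact under symmetry of the subject contrasts)
#'   or `"half"` (exactly half the subjects flip per iteration; slightly
#'   anticonservative because the scheme is not closed under composition).
#'   The scheme is isolated here so alternatives can be swapped.
#' @return data.frame with one row per effect: effect, F, df1, df2, p,
#'   pes (partial eta squared).
#' @export
permutation_mixed_anova <- function(data, dv, subject, within,
                                    between = NULL, n_perm = 10000L,
                                    seed = 1L,
                                    flip = c("independent", "half")) {
  flip <- match.arg(flip)
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a coarse p-value grid",
            call. = FALSE)
  subj <- as.character(data[[subject]])
  subjects <- unique(subj)
  n <- length(subjects)
  within_levels <- lapply(data[within], function(x) sort(unique(as.character(x))))
  names(within_levels) <- within
  ## cell order: first within factor varies fastest, matching term_contrast
  cells_df <- expand.grid(within_levels, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  cells <- do.call(paste, c(cells_df, sep = "\r"))
  cell_of <- do.call(paste, c(lapply(data[within], as.character), sep = "\r"))
  m <- length(cells)
  Y <- matrix(NA_real_, n, m, dimnames = list(subjects, cells))
  Y[cbind(match(subj, subjects), match(cell_of, cells))] <- data[[dv]]
  if (anyNA(Y)) {
    bad <- subjects[rowSums(is.na(Y)) > 0]
    stop("unbalanced design: missing cells for subject(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(between)) {
    g <- rep(1L, n)
  } else {
    glab <- data[[between]][match(subjects, subj)]
    g <- as.integer(factor(glab))
    if (length(unique(g)) < 2 || min(tabulate(g)) < 2)
      stop("need >= 2 subjects per group of '", between, "'", call. = FALSE)
  }
  k <- length(unique(g))

  draws <- with_seed(seed, {
    flips <- if (flip == "independent") {
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    } else {
      fl <- matrix(1, n_perm, n)
      half <- floor(n / 2)
      for (i in seq_len(n_perm)) fl[i, sample.int(n, half)] <- -1
      fl
    }
    list(flips = flips,
         gperms = if (k > 1) replicate(n_perm, sample(g)) else NULL)
  })
  flips <- draws$flips
  gperms <- draws$gperms

  effects <- list()
  ## between main effect: on subject means (row means of the full table)
  if (k > 1) {
    r <- rowMeans(Y)
    obs <- f_between(r, g)
    fperm <- vapply(seq_len(n_perm),
                    function(i) f_between(r, gperms[, i])["F"], numeric(1))
    effects[[between]] <- c(obs, p = perm_p(obs["F"], fperm, n_perm))
  }
  ## within terms: all non-empty subsets of the within factors
  terms <- unlist(lapply(seq_along(within), function(s)
    utils::combn(within, s, simplify = FALSE)), recursive = FALSE)
  for (term in terms) {
    C <- term_contrast(within_levels, term)
    Z <- Y %*% C
    df_term <- ncol(C)
    obs <- f_from_scores(Z, g, df_term)
    fperm_t <- numeric(n_perm)
    fperm_gt <- if (k > 1) numeric(n_perm)
    for (i in seq_len(n_perm)) {
      ft <- f_from_scores(Z * flips[i, ], g, df_term)
      fperm_t[i] <- ft$term["F"]
      if (k > 1)
        fperm_gt[i] <- f_from_scores(Z, gperms[, i], df_term)$gterm["F"]
    }
    lab <- paste(term, collapse = ":")
    effects[[lab]] <- c(obs$term,
                        p = perm_p(obs$term["F"], fperm_t, n_perm))
    if (k > 1)
      effects[[paste(between, lab, sep = ":")]] <-
        c(obs$gterm, p = perm_p(obs$gterm["F"], fperm_gt, n_perm))
  }
  out <- data.frame(effect = names(effects),
                    do.call(rbind, effects), row.names = NULL)
  out[c("effect", "F", "df1", "df2", "p", "pes")]
}

f_between <- function(r, g) {
  ng <- tabulate(g); k <- length(ng); n <- length(r)
  gm <- rowsum(r, g) / ng
  ss_b <- sum(ng * (gm - mean(r))^2)
  ss_w <- sum((r - gm[g])^2)
  c(F = (ss_b / (k - 1)) / (ss_w / (n - k)),
    df1 = k - 1, df2 = n - k, pes = ss_b / (ss_b + ss_w))
}

perm_p <- function(f_obs, f_perm, n_perm) {
  if (!is.finite(f_obs)) return(1)
  (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
}

#' Planned pairwise comparisons
#'
#' Paired t-tests for within-subject contrasts and Welch (unequal-variance)
#' t-tests for between-group contrasts, with Cohen's d computed from the SD
#' of paired differences or the pooled SD respectively.
#'
#' @param x,y the two samples; for `paired = TRUE` they must be aligned by
#'   subject.
#' @param paired within-subject (paired) contrast?
#' @param label contrast label carried into the result.
#' @return data.frame with columns contrast, t, df, p, d, n.
#' @export
planned_comparison <- function(x, y, paired = FALSE, label = "contrast") {
  ok <- if (paired) stats::complete.cases(x, y) else NULL
  if (paired) { x <- x[ok]; y <- y[ok] }
  if (length(x) < 3 || length(y) < 3)
    stop("need >= 3 observations per cell", call. = FALSE)
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0)
      stop("degenerate contrast: zero variance of paired differences",
           call. = FALSE)
    tt <- stats::t.test(x, y, paired = TRUE)
    eff <- mean(d) / stats::sd(d)
    n <- length(d)
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    eff <- (mean(x) - mean(y)) / sp
    n <- length(x) + length(y)
  }
  data.frame(contrast = label, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value, d = eff, n = n,
             stringsAsFactors = FALSE)
}

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Removes between-subject offsets before computing per-cell SEs: each
#' observation is normalized by subtracting the subject's mean and adding
#' the grand mean, then the per-cell SD is inflated by the Morey factor
#' `sqrt(m / (m - 1))` for `m` cells and divided by `sqrt(n)`.
#'
#' @param data long-format balanced data.frame.
#' @param dv response column name.
#' @param subject subject column name.
#' @param cell character vector of columns defining the within cells.
#' @return data.frame of cell means and within-subject SEs.
#' @export
within_subject_se <- function(data, dv, subject, cell) {
  cell_id <- interaction(data[cell], drop = TRUE)
  m <- nlevels(cell_id)
  if (m < 2)
    stop("within-subject SE undefined for a single cell", call. = FALSE)
  subj_mean <- stats::ave(data[[dv]], data[[subject]])
  norm <- data[[dv]] - subj_mean + mean(data[[dv]])
  morey <- sqrt(m / (m - 1))
  agg <- stats::aggregate(list(mean = data[[dv]], se_raw = norm),
                          by = data[cell],
                          FUN = mean)
  sds <- stats::aggregate(norm, by = data[cell], FUN = stats::sd)$x
  ns <- stats::aggregate(norm, by = data[cell], FUN = length)$x
  agg$se_raw <- NULL
  agg$se <- morey * sds / sqrt(ns)
  agg
}
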