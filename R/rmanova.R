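# Repeated-measures ANOVA with Huynh-Feldt sphericity adjustment, and
# Bonferroni-corrected post-hoc pairwise comparisons.
#
# Trials are averaged within participant x condition first
# (participant_means); the participant is the blocking factor, and each
# within-participant effect is tested against its own participant-by-effect
# interaction. Degrees of freedom are shrunk by the Huynh-Feldt epsilon
# estimated from the covariance of orthonormal condition contrasts.

# Orthonormal contrast matrix, (k-1) x k, rows orthogonal to the constant.
.orth_contrast <- function(k) {
  Q <- qr.Q(qr(cbind(1, stats::contr.helmert(k))))
  t(Q[, -1, drop = FALSE])
}

# Greenhouse-Geisser and Huynh-Feldt epsilons for the effect whose
# orthonormal contrast (d x k over the cells) is C; Y is n x k cell means.
.epsilons <- function(Y, C) {
  n <- nrow(Y)
  d <- nrow(C)
  S <- stats::cov(Y %*% t(C))
  gg <- sum(diag(S))^2 / (d * sum(S * S))
  hf <- (n * d * gg - 2) / (d * (n - 1) - d^2 * gg)
  list(gg = gg, hf = min(1, hf))
}

.f_and_p <- function(ss_eff, df_eff, ss_err, df_err, eps) {
  if (ss_eff == 0) {
    f <- 0
    p <- 1
  } else if (ss_err == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_eff / df_eff) / (ss_err / df_err)
    p <- stats::pf(f, df_eff * eps, df_err * eps, lower.tail = FALSE)
  }
  list(f = f, p = p)
}

#' Average trials within participant and condition
#'
#' Collapses the trial dimension of a long results table to one value per
#' (participant, task, effector, measure) cell, the level at which the
#' repeated-measures ANOVAs operate.
#'
#' @param table Long results table with columns `participant`, `task`,
#'   `trial`, `effector`, `measure`, `value`.
#' @return data.table of cell means.
#' @export
participant_means <- function(table) {
  dt <- .validate_results(table)
  dt[, .(value = mean(value)), by = .(participant, task, effector, measure)]
}

# participant x cell matrix for one measure/effector, complete-design checked.
.cells_matrix <- function(cells, cols) {
  dt <- data.table::as.data.table(cells)
  wide <- data.table::dcast(dt, participant ~ cell, value.var = "value")
  miss <- setdiff(cols, names(wide))
  if (length(miss) || anyNA(wide)) {
    stop("incomplete design: missing cell(s) ",
         paste(miss, collapse = ", "))
  }
  Y <- as.matrix(wide[, cols, with = FALSE])
  rownames(Y) <- wide$participant
  Y
}

#' Two-way repeated-measures ANOVA (finger x phalanx)
#'
#' Balanced, complete within-participant 4 x 3 design (any a x b is
#' accepted). Sums of squares are partitioned with the participant as block;
#' each effect's F uses its participant-by-effect interaction as error term,
#' and p-values are Huynh-Feldt adjusted.
#'
#' @param cells Data frame with columns `participant`, `finger`, `phalanx`,
#'   `value`, one row per participant and condition (trials already
#'   averaged, see [participant_means()]).
#' @return data.frame with one row per effect (`finger`, `phalanx`,
#'   `finger:phalanx`): sums of squares, degrees of freedom, epsilons,
#'   F and adjusted p.
#' @export
rm_anova_2way <- function(cells) {
  dt <- data.table::as.data.table(cells)
  stopifnot(all(c("participant", "finger", "phalanx", "value") %in% names(dt)))
  fl <- intersect(FINGERS, unique(dt$finger))
  pl <- intersect(PHALANGES, unique(dt$phalanx))
  if (!length(fl)) fl <- sort(unique(dt$finger))
  if (!length(pl)) pl <- sort(unique(dt$phalanx))
  a <- length(fl)
  b <- length(pl)
  dt[, cell := paste(factor(finger, fl), factor(phalanx, pl), sep = ".")]
  cols <- as.vector(t(outer(fl, pl, paste, sep = ".")))
  Y <- .cells_matrix(dt, cols) # columns ordered finger-major
  n <- nrow(Y)
  if (n < 3L) stop("fewer than 3 participants: within-participant ANOVA needs n >= 3")

  grand <- mean(Y)
  subj <- rowMeans(Y)
  MA <- sapply(seq_len(a), function(i) rowMeans(Y[, ((i - 1) * b + 1):(i * b), drop = FALSE]))
  MB <- sapply(seq_len(b), function(j) rowMeans(Y[, seq(j, a * b, by = b), drop = FALSE]))
  ma <- colMeans(MA)
  mb <- colMeans(MB)
  cellm <- colMeans(Y)

  ss_subj <- a * b * sum((subj - grand)^2)
  ss_a <- n * b * sum((ma - grand)^2)
  ss_b <- n * a * sum((mb - grand)^2)
  ss_ab <- n * sum((cellm - rep(ma, each = b) - rep(mb, a) + grand)^2)
  ss_as <- b * sum((MA - outer(subj, rep(1, a)) - outer(rep(1, n), ma) + grand)^2)
  ss_bs <- a * sum((MB - outer(subj, rep(1, b)) - outer(rep(1, n), mb) + grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_abs <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs

  CA <- .orth_contrast(a)
  CB <- .orth_contrast(b)
  CAf <- kronecker(CA, matrix(1 / sqrt(b), 1, b))
  CBf <- kronecker(matrix(1 / sqrt(a), 1, a), CB)
  CABf <- kronecker(CA, CB)

  one <- function(effect, ss_eff, d, ss_err, C) {
    eps <- .epsilons(Y, C)
    df_err <- d * (n - 1)
    fp <- .f_and_p(ss_eff, d, ss_err, df_err, eps$hf)
    data.frame(
      effect = effect, ss_effect = ss_eff, df_effect = d,
      ss_error = ss_err, df_error = df_err,
      epsilon_gg = eps$gg, epsilon_hf = eps$hf,
      df1_adj = d * eps$hf, df2_adj = df_err * eps$hf,
      f_value = fp$f, p_value = fp$p,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    one("finger", ss_a, a - 1, ss_as, CAf),
    one("phalanx", ss_b, b - 1, ss_bs, CBf),
    one("finger:phalanx", ss_ab, (a - 1) * (b - 1), ss_abs, CABf)
  )
  attr(out, "ss_total") <- ss_tot
  attr(out, "ss_participant") <- ss_subj
  attr(out, "n_participants") <- n
  out
}

#' One-way repeated-measures ANOVA on the moving effector (thumb vs finger)
#'
#' Two within-participant levels, so the test is exactly the squared paired
#' t-test and sphericity holds trivially (epsilon = 1).
#'
#' @param cells Data frame with columns `participant`, `effector` (two
#'   levels), `value`.
#' @return One-row data.frame like [rm_anova_2way()]'s.
#' @export
rm_anova_effector <- function(cells) {
  dt <- data.table::as.data.table(cells)
  stopifnot(all(c("participant", "effector", "value") %in% names(dt)))
  lev <- intersect(c("thumb", "finger"), unique(dt$effector))
  if (!length(lev)) lev <- sort(unique(dt$effector))
  if (length(unique(dt$effector)) != 2L) {
    stop("effector factor must have exactly 2 levels")
  }
  dt[, cell := as.character(effector)]
  Y <- .cells_matrix(dt, lev)
  n <- nrow(Y)
  if (n < 2L) stop("fewer than 2 participants")
  grand <- mean(Y)
  diffs <- Y[, 1] - Y[, 2]
  ss_eff <- n * sum((colMeans(Y) - grand)^2)
  ss_err <- sum((diffs - mean(diffs))^2) / 2
  fp <- .f_and_p(ss_eff, 1, ss_err, n - 1, 1)
  data.frame(
    effect = paste(lev, collapse = " vs "),
    ss_effect = ss_eff, df_effect = 1,
    ss_error = ss_err, df_error = n - 1,
    epsilon_gg = 1, epsilon_hf = 1,
    df1_adj = 1, df2_adj = n - 1,
    f_value = fp$f, p_value = fp$p,
    mean_diff = mean(diffs),
    stringsAsFactors = FALSE
  )
}

#' Huynh-Feldt epsilon of a within-participant factor
#'
#' Estimated from the covariance matrix of orthonormal condition contrasts;
#' clipped to 1 from above. With 2 levels there is a single contrast and
#' sphericity holds trivially (epsilon = 1).
#'
#' @param Y n x k matrix: participants in rows, within-factor levels in
#'   columns.
#' @return Huynh-Feldt epsilon in (0, 1].
#' @export
huynh_feldt_epsilon <- function(Y) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  n <- nrow(Y)
  if (k < 2L) stop("need at least 2 within-factor levels")
  if (n <= k - 1L) {
    warning("n <= k - 1: contrast covariance is singular; epsilon unreliable")
  }
  .epsilons(Y, .orth_contrast(k))$hf
}

#' Post-hoc pairwise comparisons of a within-participant factor
#'
#' Paired t-tests between every pair of factor levels on participant-level
#' means, with multiplicity correction (Bonferroni by default,
#' Holm available).
#'
#' @param cells Data frame with columns `participant`, a factor column named
#'   by `factor`, and `value`. If a participant has several rows per level
#'   (e.g. the other design factor), they are averaged first.
#' @param factor Name of the factor column.
#' @param method Multiplicity correction, `"bonferroni"` (default) or
#'   `"holm"`.
#' @return data.frame with one row per level pair: `level_a`, `level_b`,
#'   `mean_diff` (a minus b), `t_value`, `p_raw`, `p_adjusted`, `method`.
#' @export
posthoc_pairwise <- function(cells, factor,
                             method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(cells)
  stopifnot(all(c("participant", factor, "value") %in% names(dt)))
  dt <- dt[, .(value = mean(value)), by = c("participant", factor)]
  lev <- unique(dt[[factor]])
  # canonical ordering: radial-to-ulnar fingers, distal-to-proximal
  # phalanges, thumb before finger ("middle" is in two families, so match
  # whole level sets rather than pooled names)
  for (fam in list(FINGERS, PHALANGES, c("thumb", "finger"))) {
    if (all(lev %in% fam)) {
      lev <- intersect(fam, lev)
      break
    }
  }
  wide <- data.table::dcast(dt, stats::as.formula(paste("participant ~", factor)),
                            value.var = "value")
  if (anyNA(wide)) stop("incomplete design: missing level for some participant")
  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tval <- mean(d) / (sdd / sqrt(n))
      p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
    }
    data.frame(
      level_a = pr[1], level_b = pr[2], mean_diff = mean(d),
      t_value = tval, p_raw = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = method)
  out$method <- method
  out
}
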