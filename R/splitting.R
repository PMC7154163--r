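#' Nelson-Aalen cumulative hazard estimator
#'
#' `Lambda(t) = sum_{t_j <= t} d_j / Y_j` over the distinct event times of
#' the sample, with `d_j` events and `Y_j` subjects at risk at `t_j`.
#' Preferred here over Kaplan-Meier because tree leaves can be very small.
#'
#' @param data A data frame (typically a [as_cohort()] cohort).
#' @param time,event Column names of follow-up time and 0/1 event indicator;
#'   default to the cohort attributes when `data` is a cohort.
#' @return A tibble of class `nelson_aalen` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `increment`, `cumhaz`.  Evaluate it
#'   anywhere with [chf_at()].
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
#' na <- nelson_aalen(d)
#' chf_at(na, 3)  # 1/3 + 1 = 4/3
#' @export
nelson_aalen <- function(data, time = NULL, event = NULL) {
  v <- outcome_vectors(data, time, event)
  es <- event_summary(v$time, v$event)
  if (is.null(es)) {
    out <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), increment = numeric(0),
                          cumhaz = numeric(0))
  } else {
    out <- tibble::tibble(time = es$tj, n_risk = es$Yj, n_event = es$dj,
                          increment = es$dj / es$Yj,
                          cumhaz = cumsum(es$dj / es$Yj))
  }
  class(out) <- c("nelson_aalen", class(out))
  out
}

#' Evaluate a step cumulative hazard
#'
#' Right-continuous evaluation of a [nelson_aalen()] table (or any data
#' frame with `time` and `cumhaz` columns) at arbitrary times.
#'
#' @param chf A `nelson_aalen` tibble.
#' @param t Evaluation times.
#' @export
chf_at <- function(chf, t) {
  stopifnot(is.data.frame(chf), all(c("time", "cumhaz") %in% names(chf)))
  c(0, chf$cumhaz)[findInterval(t, chf$time) + 1L]
}

#' Plug-in null estimates for the cure model
#'
#' Under the null hypothesis of no group difference the model implies
#' `Lambda(t) = theta0 * (1 - exp(-H0(t)))`, bounded by `theta0`.  The
#' plug-ins are `theta0_hat = Lambda_hat(max event time)` (the terminal
#' Nelson-Aalen value) and
#' `H0_hat(t) = -log(1 - min(Lambda_hat(t) / theta0_hat, 1 - epsilon))`,
#' where the clamp `epsilon` keeps `H0_hat` finite at the last event time.
#'
#' @inheritParams nelson_aalen
#' @param epsilon Clamp on `Lambda_hat / theta0_hat`, default `1e-6`.
#' @return An object of class `null_estimates`: `event_times`, `cumhaz`
#'   (Nelson-Aalen at the event times), `theta0_hat`, `h0` (`H0_hat` at the
#'   event times) and `epsilon`.  Evaluate `H0_hat` anywhere with
#'   [h0_hat_at()].
#' @export
null_estimates <- function(data, time = NULL, event = NULL, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), epsilon > 0, epsilon < 1)
  v <- outcome_vectors(data, time, event)
  es <- event_summary(v$time, v$event)
  if (is.null(es)) {
    stop("null_estimates: no events in the sample (homogeneous node)")
  }
  null_estimates_from_summary(es, epsilon)
}

null_estimates_from_summary <- function(es, epsilon) {
  cumhaz <- cumsum(es$dj / es$Yj)
  theta0 <- cumhaz[length(cumhaz)]
  h0 <- -log(1 - pmin(cumhaz / theta0, 1 - epsilon))
  structure(list(event_times = es$tj, cumhaz = cumhaz,
                 theta0_hat = theta0, h0 = h0, epsilon = epsilon),
            class = "null_estimates")
}

#' @rdname null_estimates
#' @param ne A `null_estimates` object.
#' @param t Evaluation times.
#' @export
h0_hat_at <- function(ne, t) {
  stopifnot(inherits(ne, "null_estimates"))
  c(0, ne$h0)[findInterval(t, ne$event_times) + 1L]
}

# left limit H0_hat(t-): the predictable version used as score weight
h0_left_at <- function(ne, t) {
  c(0, ne$h0)[findInterval(t, ne$event_times, left.open = TRUE) + 1L]
}

#' @export
print.null_estimates <- function(x, ...) {
  cat(sprintf(
    "<null_estimates> %d event times, theta0_hat = %g, epsilon = %g\n",
    length(x$event_times), x$theta0_hat, x$epsilon))
  invisible(x)
}

#' Two-degree-of-freedom score statistic for a binary split
#'
#' Score test of no group difference under the cure model, with the
#' baseline profiled by the Nelson-Aalen plug-ins.  Over the distinct event
#' times `t_j` (group-1 at-risk `Y_1j` and events `d_1j`, totals `Y_j`,
#' `d_j`):
#' \deqn{U_\alpha = \sum_j (d_{1j} - Y_{1j} d_j / Y_j)}
#' \deqn{U_\beta  = \sum_j (1 - \hat H_0(t_j^-)) (d_{1j} - Y_{1j} d_j / Y_j)}
#' with the hypergeometric variance
#' `v_j = d_j (Y_1j/Y_j)(1 - Y_1j/Y_j)(Y_j - d_j)/(Y_j - 1)` shared across
#' components (`V_kl = sum_j w_k(t_j) w_l(t_j) v_j`, `w_alpha = 1`,
#' `w_beta = 1 - H0_hat(t-)`).  The alpha component is exactly the logrank
#' numerator (sensitive to cured-fraction differences); the beta component
#' down-weights late events and picks up differences in event dynamics.
#' The beta weight uses the left limit of the plug-in, the predictable
#' version required by the martingale central limit theorem for estimated
#' weights; it also keeps the terminal weight free of the clamp
#' `epsilon`, which otherwise dominates the variance through a single
#' event time.  The statistic is the quadratic form `U' V^- U` with a
#' generalized inverse, so `df_used` equals the rank of `V`.
#'
#' @inheritParams null_estimates
#' @param membership Logical or 0/1 vector, one entry per row of `data`,
#'   defining group 1 of the split; both groups must be nonempty.
#' @param null Optional precomputed [null_estimates()]; recomputed from the
#'   pooled sample otherwise.
#' @return An object of class `score_result`: `u` (length-2 score vector),
#'   `v` (2x2 covariance), `statistic`, `df_used`.
#' @examples
#' d <- tibble::tibble(time = c(1, 2), event = c(1, 1))
#' score_split_statistic(d, membership = c(1, 0))$statistic  # 1
#' @export
score_split_statistic <- function(data, membership, time = NULL,
                                  event = NULL, null = NULL,
                                  epsilon = 1e-6) {
  v <- outcome_vectors(data, time, event)
  m <- check_membership(membership, length(v$time))
  es <- event_summary(v$time, v$event, keep_order = TRUE)
  if (is.null(es)) stop("score_split_statistic: no events in the sample")
  ne <- null %||% null_estimates_from_summary(es, epsilon)
  comp <- split_components(es, matrix(as.numeric(m[es$ord]), ncol = 1),
                           wb = 1 - h0_left_at(ne, es$tj))
  u <- c(alpha = comp$ua[1], beta = comp$ub[1])
  vmat <- matrix(c(comp$vaa[1], comp$vab[1], comp$vab[1], comp$vbb[1]), 2, 2,
                 dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  qf <- ginv_quadform(u, vmat, rel_tol = 1e-10)
  structure(list(u = u, v = vmat, statistic = qf$statistic,
                 df_used = qf$df_used),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf(
    "<score_result> statistic = %g (df = %d), U = (%g, %g)\n",
    x$statistic, x$df_used, x$u[1], x$u[2]))
  invisible(x)
}

#' Classical logrank statistic
#'
#' One-degree-of-freedom logrank chi-square `U_alpha^2 / V_alpha,alpha`,
#' the commonly used splitting criterion for random survival forests,
#' provided for comparison modes.
#'
#' @inheritParams score_split_statistic
#' @return A nonnegative number.
#' @export
logrank_statistic <- function(data, membership, time = NULL, event = NULL) {
  v <- outcome_vectors(data, time, event)
  m <- check_membership(membership, length(v$time))
  es <- event_summary(v$time, v$event, keep_order = TRUE)
  if (is.null(es)) stop("logrank_statistic: no events in the sample")
  comp <- split_components(es, matrix(as.numeric(m[es$ord]), ncol = 1))
  if (comp$vaa[1] <= 0) 0 else comp$ua[1]^2 / comp$vaa[1]
}

#' Enumerate admissible split candidates at a node
#'
#' Candidate binary splits by variable kind: `binary` one threshold;
#' `genotype012` dominant (`{0}` vs `{1,2}`) and recessive (`{0,1}` vs
#' `{2}`); `ordered3` the two thresholds; `continuous` midpoints between
#' consecutive distinct observed values (or the three quartile cuts when
#' `quartiles = TRUE`); `categorical` one-vs-rest per observed level.
#' Candidates leaving fewer than `min_node_size` unique subjects on either
#' side are dropped.
#'
#' @param data A [as_cohort()] cohort (the node's data).
#' @param features Optional character vector restricting the variables
#'   searched.
#' @param min_node_size Minimum unique subjects per child.
#' @param quartiles Use quartile cuts instead of all midpoints for
#'   continuous variables.
#' @return Tibble with columns `variable`, `kind`, `op` (`">"` or `"=="`),
#'   `value`; zero rows when the node cannot be split.
#' @export
enumerate_candidates <- function(data, features = NULL, min_node_size = 15,
                                 quartiles = FALSE) {
  stopifnot(inherits(data, "cure_cohort"))
  cm <- cohort_matrix(data)
  vars <- feature_indices(cm, features)
  ids <- cohort_ids(data)
  cand <- node_candidates(cm$X, seq_len(nrow(cm$X)), vars, cm$kinds,
                          quartiles)
  if (is.null(cand)) return(empty_candidates(cm))
  M <- candidate_membership(cm$X, seq_len(nrow(cm$X)), cand)
  keep <- admissible_candidates(M, !duplicated(ids), min_node_size)
  cand_tibble(cand, cm, keep)
}

#' Best split at a node
#'
#' Evaluates the configured criterion on every admissible candidate and
#' returns the maximiser; ties are broken deterministically toward the
#' lowest variable (column order), then the lowest threshold.
#'
#' @inheritParams enumerate_candidates
#' @param criterion `"score"` (2-df cure-model score test) or `"logrank"`.
#' @param epsilon Clamp for the null plug-ins (score criterion).
#' @return One-row tibble `variable`, `kind`, `op`, `value`, `statistic`,
#'   `df_used`, or `NULL` when no admissible candidate exists.
#' @export
best_split <- function(data, features = NULL,
                       criterion = c("score", "logrank"),
                       min_node_size = 15, quartiles = FALSE,
                       epsilon = 1e-6) {
  stopifnot(inherits(data, "cure_cohort"))
  criterion <- match.arg(criterion)
  cm <- cohort_matrix(data)
  vars <- feature_indices(cm, features)
  bs <- node_best_split(cm$X, cohort_time(data), cohort_event(data),
                        cohort_ids(data), seq_len(nrow(cm$X)), vars,
                        cm$kinds, min_node_size, criterion, epsilon,
                        quartiles)
  if (is.null(bs)) return(NULL)
  vn <- colnames(cm$X)[bs$var]
  tibble::tibble(variable = vn, kind = unname(cm$kinds[[vn]]),
                 op = if (bs$op == "eq") "==" else ">", value = bs$value,
                 statistic = bs$statistic, df_used = bs$df_used)
}

# ---------------------------------------------------------------------------
# internal engine ------------------------------------------------------------

outcome_vectors <- function(data, time, event) {
  if (is.data.frame(data)) {
    time <- time %||% attr(data, "time_col") %||% "time"
    event <- event %||% attr(data, "event_col") %||% "event"
    stopifnot(time %in% names(data), event %in% names(data))
    list(time = data[[time]], event = data[[event]])
  } else {
    stop("expected a data frame with time and event columns")
  }
}

check_membership <- function(membership, n) {
  m <- as.logical(membership)
  if (length(m) != n || anyNA(m)) {
    stop("membership must be a complete logical/0-1 vector matching the data")
  }
  if (all(m) || !any(m)) stop("membership puts every subject on one side")
  m
}

# Distinct-event-time summary of a node.  Returns NULL when there are no
# events.  `pj` is the first index (in time order) at risk at `tj`.
event_summary <- function(time, event, keep_order = FALSE) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  ord <- order(time)
  t <- time[ord]; d <- event[ord]
  ev <- d == 1
  if (!any(ev)) return(NULL)
  tj <- unique(t[ev])
  dj <- as.integer(tabulate(match(t[ev], tj)))
  pj <- findInterval(tj, t, left.open = TRUE) + 1L
  n <- length(t)
  out <- list(tj = tj, dj = dj, pj = pj, Yj = n - pj + 1L, n = n,
              t = t, d = d)
  if (keep_order) out$ord <- ord
  out
}

# Per-candidate score components for a membership matrix M (rows already in
# the node's time order).  Returns per-candidate U_alpha, V_aa and, when a
# beta weight `wb = 1 - H0_hat(tj)` is supplied, U_beta, V_ab, V_bb.
split_components <- function(es, M, wb = NULL) {
  J <- length(es$tj)
  at_risk <- outer(es$pj, seq_len(es$n), "<=")
  storage.mode(at_risk) <- "double"
  Y1 <- at_risk %*% M                                   # J x K
  Mev <- M[es$d == 1, , drop = FALSE]
  d1 <- rowsum(Mev, group = es$t[es$d == 1])            # rows in tj order
  rate <- es$dj / es$Yj
  ome <- d1 - Y1 * rate
  cj <- ifelse(es$Yj > 1, es$dj * (es$Yj - es$dj) / (es$Yj - 1), 0)
  vj <- (Y1 * (es$Yj - Y1) / es$Yj^2) * cj
  out <- list(ua = colSums(ome), vaa = colSums(vj))
  if (!is.null(wb)) {
    out$ub <- colSums(ome * wb)
    out$vab <- colSums(vj * wb)
    out$vbb <- colSums(vj * wb^2)
  }
  out
}

# U' V^- U for a single 2x2 covariance via eigendecomposition; rank at
# relative tolerance `rel_tol`.
ginv_quadform <- function(u, v, rel_tol = 1e-10) {
  eg <- eigen(v, symmetric = TRUE)
  keep <- eg$values > rel_tol * max(eg$values, 0)
  if (!any(keep)) return(list(statistic = 0, df_used = 0L))
  proj <- drop(crossprod(eg$vectors[, keep, drop = FALSE], u))
  list(statistic = sum(proj^2 / eg$values[keep]),
       df_used = as.integer(sum(keep)))
}

# Vectorised U' V^- U over K candidates with 2x2 covariances given by
# component vectors; closed-form eigenvalues of each 2x2 matrix.
quadform_2df <- function(ua, ub, vaa, vab, vbb, rel_tol = 1e-10) {
  tr <- vaa + vbb
  det <- vaa * vbb - vab^2
  disc <- sqrt(pmax(tr^2 - 4 * det, 0))
  lmax <- (tr + disc) / 2
  lmin <- (tr - disc) / 2
  stat <- numeric(length(ua))
  df <- integer(length(ua))
  full <- lmax > 0 & lmin > rel_tol * lmax
  if (any(full)) {
    stat[full] <- (ua^2 * vbb - 2 * ua * ub * vab + ub^2 * vaa)[full] /
      det[full]
    df[full] <- 2L
  }
  r1 <- !full & lmax > 0
  if (any(r1)) {
    u1 <- vab[r1]
    u2 <- (lmax - vaa)[r1]
    axis <- abs(u1) + abs(u2) == 0        # diagonal with vbb ~ 0
    u1[axis] <- 1
    u2[axis] <- 0
    stat[r1] <- (u1 * ua[r1] + u2 * ub[r1])^2 / ((u1^2 + u2^2) * lmax[r1])
    df[r1] <- 1L
  }
  list(statistic = stat, df = df)
}

feature_indices <- function(cm, features) {
  if (is.null(features)) return(seq_len(ncol(cm$X)))
  idx <- match(features, colnames(cm$X))
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(features[is.na(idx)], collapse = ", "))
  idx
}

# Candidate list at a node: parallel vectors of variable column index,
# threshold/level value and operator.
node_candidates <- function(X, rows, vars, kinds, quartiles) {
  cvar <- integer(0); cval <- numeric(0); cop <- character(0)
  kind_v <- kinds[colnames(X)[vars]]
  fixed <- list(binary = 0.5, genotype012 = c(0.5, 1.5),
                ordered3 = c(1.5, 2.5))
  for (i in seq_along(vars)) {
    k <- kind_v[[i]]
    if (k %in% names(fixed)) {
      th <- fixed[[k]]
    } else if (k == "continuous") {
      xv <- sort(unique(X[rows, vars[i]]))
      if (length(xv) < 2) next
      th <- if (quartiles) {
        q <- unique(stats::quantile(X[rows, vars[i]],
                                    c(0.25, 0.5, 0.75), names = FALSE))
        q[q > xv[1] - 1e-12 & q < xv[length(xv)]]
      } else {
        (xv[-1] + xv[-length(xv)]) / 2
      }
      if (!length(th)) next
    } else {  # categorical: one-vs-rest per observed level
      th <- sort(unique(X[rows, vars[i]]))
      if (length(th) < 2) next
      cvar <- c(cvar, rep(vars[i], length(th)))
      cval <- c(cval, th)
      cop <- c(cop, rep("eq", length(th)))
      next
    }
    cvar <- c(cvar, rep(vars[i], length(th)))
    cval <- c(cval, th)
    cop <- c(cop, rep("gt", length(th)))
  }
  if (!length(cvar)) return(NULL)
  list(var = cvar, value = cval, op = cop)
}

# Membership matrix (node rows x candidates), group 1 = right side
# (x > threshold, or x == level).
candidate_membership <- function(X, rows, cand) {
  n <- length(rows)
  Xc <- X[rows, cand$var, drop = FALSE]
  M <- Xc > rep(cand$value, each = n)
  eq <- which(cand$op == "eq")
  if (length(eq)) {
    M[, eq] <- Xc[, eq, drop = FALSE] ==
      rep(cand$value[eq], each = n)
  }
  storage.mode(M) <- "double"
  dimnames(M) <- NULL
  M
}

# keep candidates whose both children hold >= min_node_size unique subjects
admissible_candidates <- function(M, first_occurrence, min_node_size) {
  u_total <- sum(first_occurrence)
  left_u <- colSums(M[first_occurrence, , drop = FALSE])
  left_u >= min_node_size & (u_total - left_u) >= min_node_size
}

# Full best-split search on a node of (possibly bootstrap-duplicated) rows.
# Returns NULL (leaf) or a list with the winning candidate, its statistic
# and the two children's row sets.
node_best_split <- function(X, time, event, id, rows, vars, kinds,
                            min_node_size, criterion, epsilon,
                            quartiles = FALSE) {
  t <- time[rows]; d <- event[rows]
  es <- event_summary(t, d, keep_order = TRUE)
  if (is.null(es)) return(NULL)
  cand <- node_candidates(X, rows, vars, kinds, quartiles)
  if (is.null(cand)) return(NULL)
  M <- candidate_membership(X, rows, cand)
  keep <- admissible_candidates(M, !duplicated(id[rows]), min_node_size)
  if (!any(keep)) return(NULL)
  cand <- lapply(cand, `[`, keep)
  M <- M[, keep, drop = FALSE]
  Mo <- M[es$ord, , drop = FALSE]
  if (criterion == "logrank") {
    comp <- split_components(es, Mo)
    stat <- ifelse(comp$vaa > 0, comp$ua^2 / comp$vaa, 0)
    df <- rep(1L, length(stat))
  } else {
    ne <- null_estimates_from_summary(es, epsilon)
    comp <- split_components(es, Mo, wb = 1 - c(0, ne$h0[-length(ne$h0)]))
    qf <- quadform_2df(comp$ua, comp$ub, comp$vaa, comp$vab, comp$vbb)
    stat <- qf$statistic
    df <- qf$df
  }
  stat[!is.finite(stat)] <- 0
  if (max(stat) <= 0) return(NULL)
  best <- order(-stat, cand$var, cand$value)[1L]
  memb <- M[, best] > 0
  list(var = cand$var[best], op = cand$op[best], value = cand$value[best],
       statistic = stat[best], df_used = df[best],
       left_rows = rows[!memb], right_rows = rows[memb])
}

empty_candidates <- function(cm) {
  tibble::tibble(variable = character(0), kind = character(0),
                 op = character(0), value = numeric(0))
}

cand_tibble <- function(cand, cm, keep) {
  vn <- colnames(cm$X)[cand$var]
  tibble::tibble(variable = vn, kind = unname(cm$kinds[vn]),
                 op = ifelse(cand$op == "eq", "==", ">"),
                 value = cand$value)[keep, ]
}
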