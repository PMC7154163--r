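#' Grow a single survival tree
#'
#' Recursive binary partitioning: at each node the configured criterion
#' ([score_split_statistic()] or [logrank_statistic()]) is maximised over
#' all admissible candidates among `features`; the node is split and the
#' procedure recurses.  A node becomes a leaf when it holds fewer than
#' `2 * min_node_size` unique subjects, has no events, or no candidate
#' attains a positive statistic (which covers outcome- and
#' feature-homogeneous nodes).  No depth constraint is imposed.  Bootstrap
#' duplicates (see `inbag`) are counted in the risk sets but collapsed when
#' counting "unique cases" against `min_node_size`.
#'
#' Each leaf stores the Nelson-Aalen cumulative hazard of its in-node
#' sample, evaluated on the tree's `time_grid` (all distinct training event
#' times) so tree predictions can be averaged pointwise across a forest.
#'
#' @param data A [as_cohort()] cohort.
#' @param features Optional character vector: the feature subspace this
#'   tree may use (defaults to all predictors).
#' @param min_node_size Minimum unique subjects in a terminal node
#'   (default 15).
#' @param criterion `"score"` or `"logrank"`.
#' @param quartiles Restrict continuous thresholds to quartile cuts.
#' @param epsilon Clamp for the score criterion's null plug-ins.
#' @param inbag Optional integer vector of row indices (with multiplicity)
#'   defining the bootstrap sample the tree is grown on; defaults to all
#'   rows once each.
#' @param mtry Optional: number of variables drawn (without replacement,
#'   from `features`) independently at every node, the classical
#'   random-survival-forest rule.  The default searches all of `features`
#'   at every node (the random-subspace rule).
#' @param time_grid Optional grid of times on which leaf hazards are
#'   stored; defaults to the distinct event times of `data`.
#' @return An object of class `survival_tree`.
#' @examples
#' co <- generate_cure_cohort(80, signal_spec("g", "binary", alpha = 1.5),
#'                            seed = 7)
#' tr <- grow_tree(co, min_node_size = 10, criterion = "logrank")
#' tr$n_leaves
#' @export
grow_tree <- function(data, features = NULL, min_node_size = 15,
                      criterion = c("score", "logrank"), quartiles = FALSE,
                      epsilon = 1e-6, inbag = NULL, time_grid = NULL,
                      mtry = NULL) {
  stopifnot(inherits(data, "cure_cohort"), nrow(data) >= 1)
  criterion <- match.arg(criterion)
  cm <- cohort_matrix(data)
  vars <- feature_indices(cm, features)
  search_vars <- if (is.null(mtry)) {
    vars
  } else {
    m_try <- min(mtry, length(vars))
    function() sort(sample(vars, m_try))
  }
  time <- cohort_time(data); event <- cohort_event(data)
  id <- cohort_ids(data)
  inbag <- inbag %||% seq_len(nrow(data))
  time_grid <- time_grid %||% sort(unique(time[event == 1]))
  eng <- new.env(parent = emptyenv())
  eng$leaf_chf <- list(); eng$leaf_n <- integer(0); eng$leaf_ev <- integer(0)
  root <- grow_node(cm$X, time, event, id, inbag, search_vars, cm$kinds,
                    min_node_size, criterion, epsilon, quartiles,
                    time_grid, eng)
  structure(list(
    root = root,
    features = colnames(cm$X)[sort(vars)],
    time_grid = time_grid,
    leaf_chf = do.call(rbind, eng$leaf_chf),
    leaf_n_unique = eng$leaf_n,
    leaf_n_events = eng$leaf_ev,
    n_leaves = length(eng$leaf_chf),
    inbag = inbag,
    kinds = cm$kinds, levels = cm$levels,
    min_node_size = min_node_size, criterion = criterion,
    quartiles = quartiles, epsilon = epsilon
  ), class = "survival_tree")
}

grow_node <- function(X, time, event, id, rows, vars, kinds, min_node_size,
                      criterion, epsilon, quartiles, grid, eng) {
  n_unique <- sum(!duplicated(id[rows]))
  bs <- NULL
  if (n_unique >= 2 * min_node_size) {
    svars <- if (is.function(vars)) vars() else vars
    bs <- node_best_split(X, time, event, id, rows, svars, kinds,
                          min_node_size, criterion, epsilon, quartiles)
  }
  if (is.null(bs)) {
    return(make_leaf(time[rows], event[rows], n_unique, grid, eng))
  }
  list(type = "split",
       var = colnames(X)[bs$var], op = bs$op, value = bs$value,
       statistic = bs$statistic,
       left = grow_node(X, time, event, id, bs$left_rows, vars, kinds,
                        min_node_size, criterion, epsilon, quartiles,
                        grid, eng),
       right = grow_node(X, time, event, id, bs$right_rows, vars, kinds,
                         min_node_size, criterion, epsilon, quartiles,
                         grid, eng))
}

make_leaf <- function(time, event, n_unique, grid, eng) {
  es <- event_summary(time, event)
  chf <- if (is.null(es)) {
    rep(0, length(grid))
  } else {
    c(0, cumsum(es$dj / es$Yj))[findInterval(grid, es$tj) + 1L]
  }
  leaf_id <- length(eng$leaf_chf) + 1L
  eng$leaf_chf[[leaf_id]] <- chf
  eng$leaf_n[leaf_id] <- n_unique
  eng$leaf_ev[leaf_id] <- sum(event)
  list(type = "leaf", leaf = leaf_id)
}

#' @export
print.survival_tree <- function(x, ...) {
  cat(sprintf(
    "<survival_tree> %d leaves, criterion = %s, min_node_size = %d, %d features\n",
    x$n_leaves, x$criterion, x$min_node_size, length(x$features)))
  invisible(x)
}

# Route each row of a numeric feature matrix to its leaf id.  Errors on a
# missing value at a split variable (imputation happens upstream).
route_to_leaves <- function(node, X, idx = seq_len(nrow(X))) {
  out <- integer(nrow(X))
  recurse <- function(nd, ix) {
    if (!length(ix)) return()
    if (nd$type == "leaf") {
      out[ix] <<- nd$leaf
      return()
    }
    x <- X[ix, nd$var]
    if (anyNA(x)) {
      stop("missing value for split variable '", nd$var,
           "'; impute before predicting")
    }
    memb <- if (nd$op == "eq") x == nd$value else x > nd$value
    recurse(nd$left, ix[!memb])
    recurse(nd$right, ix[memb])
  }
  recurse(node, idx)
  out
}

tree_feature_matrix <- function(tree, newdata) {
  stopifnot(is.data.frame(newdata))
  used <- tree_split_vars(tree$root)
  missing_cols <- setdiff(used, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks split variable(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cols <- lapply(names(tree$kinds), function(v) {
    if (!v %in% names(newdata)) return(rep(NA_real_, nrow(newdata)))
    x <- newdata[[v]]
    if (!is.null(tree$levels[[v]])) {
      as.numeric(factor(as.character(x), levels = tree$levels[[v]]))
    } else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(tree$kinds)
  X
}

tree_split_vars <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$var, tree_split_vars(node$left), tree_split_vars(node$right)))
}

#' Predict cumulative hazard from a tree
#'
#' Drops each subject down the tree and returns the reached leaf's
#' Nelson-Aalen cumulative hazard on the tree's time grid.
#'
#' @param tree A [grow_tree()] tree.
#' @param newdata Data frame of predictor values (must supply every split
#'   variable on the routed path, without missing values).
#' @return A numeric matrix, subjects x grid times, with the grid as column
#'   names.  Use the `predict()` method for a tidy long format.
#' @export
predict_chf <- function(tree, newdata) {
  stopifnot(inherits(tree, "survival_tree"))
  X <- tree_feature_matrix(tree, newdata)
  leaves <- route_to_leaves(tree$root, X)
  out <- tree$leaf_chf[leaves, , drop = FALSE]
  dimnames(out) <- list(NULL, format_grid(tree$time_grid))
  out
}

#' @export
#' @rdname predict_chf
#' @param object,... Method arguments: `object` is the tree, `newdata` as
#'   above.
predict.survival_tree <- function(object, newdata, ...) {
  m <- predict_chf(object, newdata)
  chf_long(m, object$time_grid)
}

chf_long <- function(m, grid, value_name = "chf") {
  out <- tidyr::expand_grid(.row = seq_len(nrow(m)), time = grid)
  out[[value_name]] <- as.vector(t(m))
  out
}

format_grid <- function(grid) formatC(grid, format = "g", digits = 8)
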