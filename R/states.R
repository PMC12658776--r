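#' Parameters of connectivity-state clustering
#'
#' Windows are clustered with k-means under the L1 (cityblock) distance —
#' robust in high dimension — with the element-wise median as the
#' L1-optimal centroid update. Initialization is two-phase: a first fit on
#' "exemplar" windows (local maxima of the spatial connectivity variance
#' across windows), then a full-data fit started from the exemplar
#' centroids. The number of states is chosen from the subject
#' participation-rate profile rather than an elbow/Silhouette criterion;
#' see [select_k_and_retain()].
#'
#' @param k_range candidate numbers of states (default 2..8).
#' @param n_init random restarts of the exemplar-phase initialization.
#' @param max_iter Lloyd iteration cap.
#' @param pr_threshold participation rate at or above which a state counts
#'   as a population-level (retained) state. A choice of this package, not
#'   an empirical constant; 0.5 by default.
#' @param rare_max a state visited by at most this many subjects counts as
#'   idiosyncratic rather than population-level.
#' @param rng_seed integer seed for the restarts.
#' @export
state_params <- function(k_range = 2:8, n_init = 10, max_iter = 300,
                         pr_threshold = 0.5, rare_max = 1, rng_seed = 1L) {
  stopifnot(all(k_range >= 1), n_init >= 1, max_iter >= 1,
            pr_threshold >= 0, pr_threshold <= 1, rare_max >= 0)
  structure(as.list(environment()), class = "state_params")
}

#' Spatial variance of each window's connectivity map
#'
#' @param dfc a `dfc_series` from [compute_dfc_series()].
#' @return numeric vector, one variance per window (over valid voxels).
#' @export
window_variance_series <- function(dfc) {
  apply(dfc$maps[dfc$valid, , drop = FALSE], 2, stats::var)
}

#' Local maxima of a variance series (exemplar windows)
#'
#' Strict interior local maxima; a flat plateau that is a maximum
#' contributes its first index; endpoints never qualify. An empty result is
#' legitimate (e.g. monotone series).
#'
#' @param v numeric vector, length >= 3.
#' @return integer vector of indices.
#' @export
select_exemplars <- function(v) {
  n <- length(v)
  stopifnot(n >= 3)
  out <- integer(0)
  w <- 2L
  while (w <= n - 1L) {
    if (v[w] > v[w - 1L]) {
      e <- w
      while (e < n && v[e + 1L] == v[w]) e <- e + 1L
      if (e < n && v[w] > v[e + 1L]) out <- c(out, w)
      w <- e + 1L
    } else {
      w <- w + 1L
    }
  }
  out
}

# one Lloyd run under L1; returns model with objective trace
lloyd_l1 <- function(X, C, max_iter) {
  n <- nrow(X)
  labels_old <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    a <- l1_assign_cpp(X, C)
    trace <- c(trace, a$objective)
    if (identical(a$labels, labels_old)) break
    labels_old <- a$labels
    C_new <- group_col_medians_cpp(X, a$labels, nrow(C))
    empty <- which(is.na(C_new[, 1]))
    if (length(empty) > 0) {
      far <- order(a$dist, decreasing = TRUE)[seq_along(empty)]
      C_new[empty, ] <- X[far, , drop = FALSE]
    }
    C <- C_new
  }
  a <- l1_assign_cpp(X, C)
  list(centroids = C, labels = a$labels, objective = a$objective,
       trace = c(trace, a$objective))
}

#' L1 k-means over pooled connectivity windows
#'
#' Two-phase exemplar-initialized fit (see [state_params()]); the best of
#' `n_init` restarts by final objective is returned. With fewer exemplars
#' than k, initial centroids are sampled from all windows instead (logged
#' in the result).
#'
#' @param X windows x features matrix (rows are flattened z-maps).
#' @param k number of states (k <= nrow(X)).
#' @param params a [state_params()].
#' @param exemplar_idx indices of exemplar windows (possibly empty).
#' @return list of class `state_model`: `k`, `centroids` (k x features),
#'   `labels` (per window), `objective`, `objective_trace`,
#'   `exemplar_idx`, `init` ("exemplar" or "sampled").
#' @export
kmeans_l1 <- function(X, k, params = state_params(),
                      exemplar_idx = integer(0)) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of windows")
  set.seed(params$rng_seed)
  use_exemplars <- length(exemplar_idx) >= k
  best <- NULL
  for (i in seq_len(params$n_init)) {
    if (use_exemplars) {
      init_rows <- sample(exemplar_idx, k)
      ph1 <- lloyd_l1(X[exemplar_idx, , drop = FALSE],
                      X[init_rows, , drop = FALSE], params$max_iter)
      fit <- lloyd_l1(X, ph1$centroids, params$max_iter)
    } else {
      init_rows <- sample(nrow(X), k)
      fit <- lloyd_l1(X, X[init_rows, , drop = FALSE], params$max_iter)
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(k = k, centroids = best$centroids, labels = best$labels,
                 objective = best$objective,
                 objective_trace = best$trace,
                 exemplar_idx = exemplar_idx,
                 init = if (use_exemplars) "exemplar" else "sampled"),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d (%s init), objective %.4g, sizes: %s\n",
              x$k, x$init, x$objective,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Subject participation rate of each state
#'
#' PR of a state = fraction of subjects contributing at least one window.
#'
#' @param labels per-window state labels (1..k).
#' @param subject_of_window per-window subject ids.
#' @param k number of states (default: max label).
#' @return numeric vector of length k.
#' @export
participation_rate <- function(labels, subject_of_window, k = max(labels)) {
  subjects <- unique(subject_of_window)
  n_sub <- length(subjects)
  vapply(seq_len(k), function(s) {
    length(unique(subject_of_window[labels == s])) / n_sub
  }, numeric(1))
}

#' Choose the number of states from participation rates
#'
#' Every candidate k in `params$k_range` is fitted. A solution is
#' admissible when each of its states is either population-level
#' (PR >= `pr_threshold`) or idiosyncratic (visited by at most `rare_max`
#' subjects) — a state with middling participation signals over-splitting.
#' Among admissible solutions with at least two retained states and every
#' subject contributing to at least one retained state, the largest k wins.
#'
#' @param X windows x features matrix.
#' @param subject_of_window per-window subject ids.
#' @param params a [state_params()].
#' @param exemplar_idx pooled exemplar window indices.
#' @param fix_k optional integer overriding the selection rule.
#' @return list: `k`, `model` (the chosen [kmeans_l1()] fit), `retained`
#'   (state ids with PR >= threshold), `pr_table` (one row per k and
#'   state), `participation` (PR vector of the chosen fit).
#' @export
select_k_and_retain <- function(X, subject_of_window,
                                params = state_params(),
                                exemplar_idx = integer(0),
                                fix_k = NULL) {
  n_sub <- length(unique(subject_of_window))
  fits <- list()
  rows <- list()
  k_cands <- if (is.null(fix_k)) params$k_range else fix_k
  for (k in k_cands) {
    model <- kmeans_l1(X, k, params, exemplar_idx)
    pr <- participation_rate(model$labels, subject_of_window, k)
    n_subj_state <- round(pr * n_sub)
    retained <- which(pr >= params$pr_threshold)
    idio <- which(n_subj_state <= params$rare_max)
    covered <- all(subject_of_window %in%
                     subject_of_window[model$labels %in% retained])
    admissible <- all(seq_len(k) %in% union(retained, idio)) &&
      length(retained) >= 2 && covered
    fits[[as.character(k)]] <- list(model = model, pr = pr,
                                    retained = retained,
                                    admissible = admissible)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, state = seq_len(k), pr = pr, n_subjects = n_subj_state,
      retained = seq_len(k) %in% retained, admissible = admissible)
  }
  pr_table <- do.call(rbind, rows)
  if (!is.null(fix_k)) {
    f <- fits[[as.character(fix_k)]]
    return(list(k = fix_k, model = f$model, retained = f$retained,
                participation = f$pr, pr_table = pr_table))
  }
  ok <- vapply(fits, function(f) f$admissible, logical(1))
  if (!any(ok)) {
    print(pr_table)
    stop("no candidate k satisfies the participation-rate rule; ",
         "PR tables printed above")
  }
  k_best <- max(as.integer(names(fits)[ok]))
  f <- fits[[as.character(k_best)]]
  list(k = k_best, model = f$model, retained = f$retained,
       participation = f$pr, pr_table = pr_table)
}

#' Per-subject mean map of each retained state
#'
#' Averages each subject's windows assigned to a retained state; subjects
#' with no window in a state yield an NA row (they are dropped from that
#' state's group test, with the count recorded in `missing`).
#'
#' @param X windows x features matrix.
#' @param labels per-window state labels.
#' @param subject_of_window per-window subject ids.
#' @param retained state ids to summarize.
#' @return list with `maps` (list per state of subjects x features
#'   matrices), `subjects`, `missing` (per state, ids without windows).
#' @export
subject_state_mean_maps <- function(X, labels, subject_of_window, retained) {
  subjects <- unique(subject_of_window)
  maps <- list()
  missing <- list()
  for (s in retained) {
    M <- matrix(NA_real_, length(subjects), ncol(X))
    rownames(M) <- subjects
    for (i in seq_along(subjects)) {
      rows <- which(subject_of_window == subjects[i] & labels == s)
      if (length(rows) > 0)
        M[i, ] <- colMeans(X[rows, , drop = FALSE])
    }
    maps[[as.character(s)]] <- M
    missing[[as.character(s)]] <- subjects[rowSums(!is.na(M)) == 0]
  }
  list(maps = maps, subjects = subjects, missing = missing)
}

#' Pool dFC windows of several subjects into one feature matrix
#'
#' Features are the Fisher-z values over the valid voxels common to all
#' subjects (intersection mask), so L1 distances compare like with like
#' even when lesions differ.
#'
#' @param dfc_list list of `dfc_series`.
#' @return list: `X` (total windows x common voxels), `subject_of_window`,
#'   `window_of_row`, `common_valid` (logical vector over the grid),
#'   `exemplar_idx` (pooled local-variance maxima, row indices of `X`),
#'   `grid_dims`.
#' @export
pool_dfc_features <- function(dfc_list) {
  common <- Reduce(`&`, lapply(dfc_list, `[[`, "valid"))
  if (!any(common)) stop("no voxel is valid in every subject")
  Xs <- lapply(dfc_list, function(d) t(d$maps[common, , drop = FALSE]))
  X <- do.call(rbind, Xs)
  n_win <- vapply(Xs, nrow, integer(1))
  subject_of_window <- rep(vapply(dfc_list, `[[`, "", "subject_id"), n_win)
  window_of_row <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  offs <- cumsum(c(0, n_win[-length(n_win)]))
  exemplar_idx <- unlist(lapply(seq_along(dfc_list), function(i) {
    v <- window_variance_series(dfc_list[[i]])
    offs[i] + select_exemplars(v)
  }), use.names = FALSE)
  list(X = X, subject_of_window = subject_of_window,
       window_of_row = window_of_row, common_valid = common,
       exemplar_idx = as.integer(exemplar_idx),
       grid_dims = dfc_list[[1]]$grid_dims)
}
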