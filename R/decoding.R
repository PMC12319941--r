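#' Enumerate split-half folds of the usable runs
#'
#' All unordered partitions of the usable runs into two complementary halves
#' of (as near as possible) equal size: `floor(n/2)` vs `ceiling(n/2)` runs.
#' Eight runs give 35 4-vs-4 folds; five runs give 10 2-vs-3 folds.
#'
#' @param runs Vector of usable run ids (length >= 2).
#' @return A tibble with columns `fold`, `half_a`, `half_b` (list-columns of
#'   run ids).
#' @examples
#' nrow(enumerate_folds(1:8)) # 35
#' @export
enumerate_folds <- function(runs) {
  runs <- sort(unique(runs))
  n <- length(runs)
  if (n < 2)
    stop("split-half folds require at least 2 usable runs", call. = FALSE)
  k <- floor(n / 2)
  combs <- utils::combn(runs, k, simplify = FALSE)
  if (n %% 2 == 0) {
    combs <- purrr::keep(combs, ~ runs[1] %in% .x)
  }
  tibble::tibble(
    fold = seq_along(combs),
    half_a = combs,
    half_b = purrr::map(combs, ~ setdiff(runs, .x))
  )
}

#' Cross-split Euclidean distance matrix for one fold
#'
#' Entry (i, j) is the Euclidean distance between condition i's mean voxel
#' pattern in one half of the runs and condition j's mean pattern in the
#' other half, including i = j (the diagonal is a within-condition
#' cross-split distance and is generally positive under noise). The matrix
#' is symmetrized over fold orientation, `(d_AB + d_BA) / 2`, so results do
#' not depend on which half is labeled A.
#'
#' @param half_a,half_b Voxels x conditions mean-pattern matrices from the
#'   two halves (same voxels, same conditions).
#' @return A conditions x conditions distance matrix (arbitrary units).
#' @export
cross_split_distances <- function(half_a, half_b) {
  if (!identical(dim(half_a), dim(half_b)) ||
      !identical(rownames(half_a), rownames(half_b)))
    stop("halves disagree on the voxel set", call. = FALSE)
  if (!identical(colnames(half_a), colnames(half_b)))
    stop("halves disagree on the condition set", call. = FALSE)
  a2 <- colSums(half_a^2)
  b2 <- colSums(half_b^2)
  d2 <- outer(a2, b2, `+`) - 2 * crossprod(half_a, half_b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (d + t(d)) / 2
}

#' Average distance matrices over folds
#'
#' @param folds List of conditions x conditions matrices, one per fold.
#' @return Their element-wise mean.
#' @export
average_over_folds <- function(folds) {
  if (length(folds) < 1) stop("no fold matrices to average", call. = FALSE)
  average_matrices(folds)
}

#' Hypothesis matrix for a decoding scheme
#'
#' Labels every ordered condition pair (self-pairs included) as `within`,
#' `between`, or `excluded`:
#'
#' * `affordance_overall` -- translation conditions 1-6 only (turns change
#'   the affordance's hemifield mid-trial); within = pairs sharing the
#'   doorway side (both: 1,4; left: 2,5; right: 3,6) including self-pairs;
#'   between = all other pairs among 1-6.
#' * `affordance_generalize` -- as above restricted to pairs that differ in
#'   ego-motion (one forward, one backward), so decoding must generalize
#'   over motion direction; same-ego-motion pairs (including self-pairs) are
#'   excluded.
#' * `egomotion_overall` -- groups forward (1-3), backward (4-6), left turn
#'   (7,8), right turn (9,10); within = same-direction pairs and self-pairs;
#'   between = only the closely matched pairs -- forward vs backward, and
#'   left vs right turns; all other pairs excluded.
#' * `egomotion_generalize` -- as above with every pair additionally
#'   required to differ in doorway side (generalization over affordance);
#'   self-pairs drop out.
#' * `conflict` -- turn conditions only; within = pairs sharing
#'   consistency status (consistent: 7,10; inconsistent: 8,9) including
#'   self-pairs; between = consistent vs inconsistent pairs.
#' * `room_texture` -- defined over the 8 room types of room-resolved
#'   patterns; within = same room (cross-split self-pairs), between =
#'   different rooms.
#'
#' @param scheme Scheme name (see above).
#' @return An object of class `hypothesis_matrix`: a labels matrix with the
#'   scheme name attached. `as_tibble()` gives the pair list; `autoplot()`
#'   draws it.
#' @export
build_hypothesis_matrix <- function(scheme = c("affordance_overall",
                                               "affordance_generalize",
                                               "egomotion_overall",
                                               "egomotion_generalize",
                                               "conflict",
                                               "room_texture")) {
  scheme <- match.arg(scheme)
  ct <- condition_table()
  if (scheme == "room_texture") {
    ids <- 1:8
    lab <- matrix("between", 8, 8, dimnames = list(ids, ids))
    diag(lab) <- "within"
    return(new_hypothesis_matrix(lab, scheme))
  }
  ids <- ct$condition_id
  aff <- ct$affordance
  ego <- ct$ego_motion
  trans <- ego %in% c("forward", "backward")
  turn <- !trans
  lab <- matrix("excluded", 10, 10, dimnames = list(ids, ids))
  for (i in 1:10) for (j in 1:10) {
    lab[i, j] <- switch(
      scheme,
      affordance_overall = if (trans[i] && trans[j]) {
        if (aff[i] == aff[j]) "within" else "between"
      } else "excluded",
      affordance_generalize = if (trans[i] && trans[j] && ego[i] != ego[j]) {
        if (aff[i] == aff[j]) "within" else "between"
      } else "excluded",
      egomotion_overall = if (ego[i] == ego[j]) "within"
        else if (matched_ego_pair(ego[i], ego[j])) "between"
        else "excluded",
      egomotion_generalize = if (aff[i] == aff[j]) "excluded"
        else if (ego[i] == ego[j]) "within"
        else if (matched_ego_pair(ego[i], ego[j])) "between"
        else "excluded",
      conflict = if (turn[i] && turn[j]) {
        if (ct$consistency[i] == ct$consistency[j]) "within" else "between"
      } else "excluded"
    )
  }
  new_hypothesis_matrix(lab, scheme)
}

matched_ego_pair <- function(a, b) {
  (all(c(a, b) %in% c("forward", "backward"))) ||
    (all(c(a, b) %in% c("left_turn", "right_turn")))
}

new_hypothesis_matrix <- function(lab, scheme) {
  if (!any(lab == "within") || !any(lab == "between"))
    stop("hypothesis matrix must label at least one within and one between pair",
         call. = FALSE)
  structure(lab, scheme = scheme, class = c("hypothesis_matrix", "matrix"))
}

#' @export
print.hypothesis_matrix <- function(x, ...) {
  cat("<hypothesis_matrix>", attr(x, "scheme"), "\n")
  short <- matrix(substr(unclass(x), 1, 1), nrow(x),
                  dimnames = dimnames(x))
  print(short, quote = FALSE)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.hypothesis_matrix <- function(x, ...) {
  ids <- as.integer(rownames(x))
  tidyr::expand_grid(cond_a = ids, cond_b = ids) |>
    dplyr::mutate(label = as.vector(t(unclass(x))),
                  scheme = attr(x, "scheme"))
}

#' Score a decoding scheme on a distance matrix
#'
#' The within-minus-between difference score: unweighted mean of the
#' distance-matrix cells labeled `between` minus the mean of the cells
#' labeled `within`. Positive scores mean smaller cross-split distances for
#' same-information pairs, i.e. the patterns carry the scheme's information.
#'
#' @param distances Conditions x conditions matrix (fold-averaged).
#' @param hypothesis A [build_hypothesis_matrix()] object with matching
#'   condition set.
#' @return One-row tibble: `scheme`, `within_mean`, `between_mean`, `diff`.
#' @export
score_decoding <- function(distances, hypothesis) {
  if (!identical(dim(distances), dim(unclass(hypothesis))))
    stop("hypothesis labels do not cover the distance matrix's condition set",
         call. = FALSE)
  lab <- unclass(hypothesis)
  w <- distances[lab == "within"]
  b <- distances[lab == "between"]
  if (!length(w) || !length(b))
    stop("scheme labels no within or no between cells", call. = FALSE)
  tibble::tibble(scheme = attr(hypothesis, "scheme"),
                 within_mean = mean(w), between_mean = mean(b),
                 diff = mean(b) - mean(w))
}

#' Split-half cross-validated condition distances per subject and ROI
#'
#' For each subject x ROI: concatenates the two hemispheres' voxel patterns,
#' averages the run betas within each half of every split-half fold,
#' computes the cross-split Euclidean distance matrix, and averages it over
#' all folds.
#'
#' @param betas A beta table ([simulate_betas()], [fit_experiment_glm()], or
#'   compatible), optionally already restricted to usable runs.
#' @param scenarios Optional [usable_run_scenarios()] table applied first.
#' @return A tibble with columns `subject`, `roi`, `n_folds`, and
#'   `distances` (list of condition x condition matrices).
#' @export
subject_distances <- function(betas, scenarios = NULL) {
  if (!is.null(scenarios)) betas <- apply_usable_runs(betas, scenarios)
  key <- paste(betas$subject, betas$roi, sep = "\r")
  idx <- split(seq_len(nrow(betas)), factor(key, levels = unique(key)))
  firsts <- vapply(idx, function(i) i[[1]], integer(1))
  out_nf <- integer(length(idx))
  out_d <- vector("list", length(idx))
  for (ii in seq_along(idx)) {
    rows <- idx[[ii]]
    runs <- betas$run[rows]
    urun <- sort(unique(runs))
    mats <- lapply(urun, function(r) {
      rr <- rows[runs == r]
      rr <- rr[order(betas$hemisphere[rr])]
      if (length(rr) == 1) betas$betas[[rr]]
      else do.call(rbind, betas$betas[rr])
    })
    dm <- dim(mats[[1]])
    if (!all(vapply(mats, function(m) identical(dim(m), dm), logical(1))))
      stop("voxel sets differ across runs; cannot average", call. = FALSE)
    fi <- fold_indices(length(urun))
    n_half_a <- length(fi$a[[1]])
    n_half_b <- length(urun) - n_half_a
    total <- Reduce(`+`, mats)
    acc <- 0
    for (f in seq_along(fi$a)) {
      sa <- Reduce(`+`, mats[fi$a[[f]]])
      A <- sa / n_half_a
      B <- (total - sa) / n_half_b
      a2 <- colSums(A^2)
      d2 <- outer(a2, colSums(B^2), `+`) - 2 * crossprod(A, B)
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      acc <- acc + (d + t(d)) / 2
    }
    D <- acc / length(fi$a)
    dimnames(D) <- list(colnames(mats[[1]]), colnames(mats[[1]]))
    out_nf[ii] <- length(fi$a)
    out_d[[ii]] <- D
  }
  tibble::tibble(subject = betas$subject[firsts], roi = betas$roi[firsts],
                 n_folds = out_nf, distances = out_d)
}

# Memoized complementary half-partitions of n runs, as index vectors for
# half A (half B is the complement); matches enumerate_folds().
.fold_cache <- new.env(parent = emptyenv())
fold_indices <- function(n) {
  k <- as.character(n)
  if (!is.null(.fold_cache[[k]])) return(.fold_cache[[k]])
  f <- enumerate_folds(seq_len(n))
  res <- list(a = f$half_a, b = f$half_b)
  .fold_cache[[k]] <- res
  res
}

#' Decode condition information from split-half pattern distances
#'
#' Runs the full multivariate analysis: fold-averaged cross-split distance
#' matrices per subject and ROI ([subject_distances()]), scored under each
#' requested hypothesis scheme ([score_decoding()]).
#'
#' @inheritParams subject_distances
#' @param schemes Character vector of scheme names (see
#'   [build_hypothesis_matrix()]); `room_texture` requires room-resolved
#'   betas (`simulate_betas(..., by = "room")` or a room-resolved GLM).
#' @return A tibble with columns `subject`, `roi`, `scheme`, `within_mean`,
#'   `between_mean`, `diff`; the fold-averaged distance matrices are
#'   attached as attribute `"distances"`.
#' @examples
#' cfg <- sim_config(n_subjects = 3, n_voxels = 10, n_runs = 4,
#'                   rois = "OPA", seed = 2)
#' simulate_betas(cfg) |> decode_patterns(schemes = "affordance_overall")
#' @export
decode_patterns <- function(betas,
                            schemes = c("affordance_overall",
                                        "affordance_generalize",
                                        "egomotion_overall",
                                        "egomotion_generalize",
                                        "conflict"),
                            scenarios = NULL) {
  dists <- subject_distances(betas, scenarios)
  hyps <- purrr::map(schemes, build_hypothesis_matrix)
  out <- purrr::map(hyps, function(h) {
    lab <- unclass(h)
    if (!identical(dim(dists$distances[[1]]), dim(lab)))
      stop("hypothesis labels do not cover the distance matrix's condition set",
           call. = FALSE)
    wmask <- lab == "within"
    bmask <- lab == "between"
    w <- vapply(dists$distances, function(D) mean(D[wmask]), numeric(1))
    b <- vapply(dists$distances, function(D) mean(D[bmask]), numeric(1))
    dplyr::bind_cols(dists[, c("subject", "roi")],
                     tibble::tibble(scheme = attr(h, "scheme"),
                                    within_mean = w, between_mean = b,
                                    diff = b - w))
  })
  structure(dplyr::bind_rows(out), distances = dists)
}

#' Group-level decoding test
#'
#' One-tailed (by default) paired t-test of within vs between mean
#' distances -- equivalently a one-sample t of the difference scores against
#' zero, in the direction of positive decoding -- per ROI and scheme.
#'
#' @param scores Output of [decode_patterns()].
#' @param tails 1 (default, directional: diff > 0) or 2.
#' @return A tidy tibble: `roi`, `scheme`, `n`, `mean_diff`, `t`, `df`, `p`.
#' @export
group_decoding_test <- function(scores, tails = 1) {
  key <- paste(scores$roi, scores$scheme, sep = "\r")
  idx <- split(seq_len(nrow(scores)), factor(key, levels = sort(unique(key))))
  rows <- lapply(idx, function(ix) {
    if (length(ix) < 3)
      stop("group decoding test requires at least 3 subjects", call. = FALSE)
    tt <- paired_t(scores$between_mean[ix], scores$within_mean[ix],
                   tails = tails, direction = "greater")
    tibble::tibble(roi = scores$roi[ix[1]], scheme = scores$scheme[ix[1]],
                   n = length(ix), mean_diff = mean(scores$diff[ix]),
                   t = tt$t, df = tt$df, p = tt$p)
  })
  dplyr::bind_rows(rows)
}
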