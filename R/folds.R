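# Subject-level cross-validation machinery: nested (outer x inner) fold
# plans and the final k-way split used to obtain the ensemble members.

split_chunks <- function(x, k) {
  n <- length(x)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(x[starts[i]:ends[i]]))
}

#' Nested cross-validation fold plan
#'
#' Splits subjects into `n_outer` disjoint test sets covering everyone;
#' within each outer fold the remaining subjects are split into `n_inner`
#' disjoint, equal-sized (within 1) validation sets with the complement as
#' training set.  Deterministic for a given seed.
#'
#' @param n_subjects number of subjects (indices `1:n_subjects`).
#' @param n_outer,n_inner fold counts (default 3 x 5).
#' @param seed RNG seed.
#' @return List of class `lc_foldplan`: element `outer[[o]]` has `test`,
#'   `trainval`, and `inner`, a list of `n_inner` lists with `train`/`val`.
#' @export
make_fold_plan <- function(n_subjects, n_outer = 3, n_inner = 5, seed = 1) {
  if (n_subjects < n_outer * n_inner)
    lcseg_error("lcseg_argument_error",
                sprintf("need at least %d subjects for %d x %d folds",
                        n_outer * n_inner, n_outer, n_inner))
  with_seed(seed, {
    perm <- sample(n_subjects)
    tests <- split_chunks(perm, n_outer)
    outer <- lapply(seq_len(n_outer), function(o) {
      trainval <- sort(setdiff(seq_len(n_subjects), tests[[o]]))
      vperm <- sample(trainval)
      vals <- split_chunks(vperm, n_inner)
      inner <- lapply(vals, function(v)
        list(train = sort(setdiff(trainval, v)), val = v))
      list(test = tests[[o]], trainval = trainval, inner = inner)
    })
    structure(list(outer = outer, n_subjects = n_subjects,
                   n_outer = n_outer, n_inner = n_inner, seed = seed),
              class = "lc_foldplan")
  })
}

#' Final k-way training split
#'
#' Splits all subjects into `k` equal-sized (within 1) validation subsets;
#' member `i` trains on everything except validation subset `i`.  This is
#' the split that produces the `k = 5` ensemble members.
#'
#' @param n_subjects number of subjects.
#' @param k number of members (default 5).
#' @param seed RNG seed.
#' @return List of `k` lists with `train` and `val` index vectors.
#' @export
make_final_split <- function(n_subjects, k = 5, seed = 1) {
  if (n_subjects < k)
    lcseg_error("lcseg_argument_error",
                sprintf("need at least %d subjects for %d subsets", k, k))
  with_seed(seed, {
    perm <- sample(n_subjects)
    vals <- split_chunks(perm, k)
    lapply(vals, function(v)
      list(train = sort(setdiff(seq_len(n_subjects), v)), val = v))
  })
}
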