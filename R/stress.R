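#' Jaccard distance between two author sets
#'
#' The Jaccard distance `1 - |X n Y| / |X u Y|` between two sets of author
#' identifiers.  It is 0 exactly when the sets are equal and 1 when they are
#' disjoint; author order never matters.
#'
#' @param x,y Character vectors of author identifiers (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard_distance(c("a1", "a2", "a3"), c("a1", "a2", "a4"))  # 0.5
#' @export
jaccard_distance <- function(x, y) {
  x <- as_author_set(x)
  y <- as_author_set(y)
  u <- length(union(x, y))
  if (u == 0L) {
    stop_citesum("Jaccard distance is undefined when both author sets are empty",
                 "citesum_empty_union")
  }
  1 - length(intersect(x, y)) / u
}

#' Partition the contributors of a family of author sets by membership count
#'
#' For a family (multiset) `T` of author sets, returns for each
#' `i = 1, ..., |T|` the set of authors who belong to exactly `i` members of
#' `T`.  These sets partition the union of `T`; the last one equals the
#' intersection of `T`.
#'
#' @param sets A list of character vectors, one author set per member.
#'   Repeated identical sets are meaningful (multiset semantics).
#' @return A list of length `length(sets)`; element `i` is the sorted
#'   character vector of authors contributing to exactly `i` members.
#' @examples
#' membership_partition(list(c("b","c","d"), c("a","c","d"),
#'                           c("a","b","d"), c("a","b","c")))
#' @export
membership_partition <- function(sets) {
  sets <- check_family(sets)
  n <- length(sets)
  counts <- table(unlist(lapply(sets, as_author_set), use.names = FALSE))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- sort(names(counts)[counts == i])
  }
  names(out) <- as.character(seq_len(n))
  out
}

#' Stress of a family of author sets
#'
#' The multiset generalisation of the Jaccard distance:
#' `stress(T) = 1 - |intersection(T)| / |union(T)|`.  It is 0 exactly when
#' all member sets are equal, 1 when no author is common to every member,
#' and monotone under multiset inclusion: enlarging the family can never
#' lower the stress.
#'
#' @inheritParams membership_partition
#' @return A number in `[0, 1]`.
#' @seealso [stress_alpha()] for the weighted relaxation,
#'   [stress_report()] for per-node diagnostics on a hierarchy.
#' @examples
#' stress(list(c("a","b"), c("a","b"), c("a","b")))  # 0
#' stress(list(c("a3","a4"), c("a1","a2","a3"), c("a1","a2","a4")))  # 1
#' @export
stress <- function(sets) {
  sets <- check_family(sets)
  uni <- Reduce(union, sets)
  1 - length(Reduce(intersect, sets)) / length(uni)
}

#' Weighted (alpha) stress of a family of author sets
#'
#' A relaxation of [stress()] that gives partial credit to authors who
#' contributed to many, but not all, members of the family:
#' `stress_alpha(T) = 1 - sum_i alpha(|T|, i) * |F(T, i)| / |union(T)|`,
#' where `F(T, i)` is the set of authors in exactly `i` members (see
#' [membership_partition()]).  With the indicator weight it reduces to
#' [stress()]; any weight satisfying the conditions checked by
#' [check_alpha_monotone()] yields a measure that is again monotone under
#' multiset inclusion.
#'
#' @inheritParams membership_partition
#' @param alpha A weight function `function(n, i)` with values in `[0, 1]`,
#'   or the name of a built-in one (see [alpha_function()]).
#' @return A number in `[0, 1]` provided `alpha(n, n) = 1`.
#' @examples
#' T4 <- list(c("b","c","d"), c("a","c","d"), c("a","b","d"), c("a","b","c"))
#' stress_alpha(T4, "exponential")  # 0.5
#' stress_alpha(T4, "indicator") == stress(T4)
#' @export
stress_alpha <- function(sets, alpha = "indicator") {
  sets <- check_family(sets)
  alpha <- alpha_function(alpha)
  n <- length(sets)
  part <- membership_partition(sets)
  sizes <- lengths(part)
  w <- vapply(seq_len(n), function(i) alpha(n, i), numeric(1))
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop_citesum("alpha(n, i) must lie in [0, 1] for 1 <= i <= n",
                 "citesum_bad_alpha")
  }
  1 - sum(w * sizes) / sum(sizes)
}

#' Built-in stress weight functions
#'
#' Weight functions `alpha(n, i)` for [stress_alpha()], registered by name
#' for configuration files and the command line:
#' \describe{
#'   \item{`indicator`}{1 if `i = n`, else 0 — recovers plain [stress()].}
#'   \item{`linear`}{`1 / (n + 1 - i)` — credit decays harmonically with the
#'     number of missed members.}
#'   \item{`exponential`}{`2^(i - n)` — credit halves per missed member.}
#' }
#' All three satisfy `alpha(n, n) = 1` and the monotonicity conditions of
#' [check_alpha_monotone()].
#'
#' @param name A registered weight name, or a function `function(n, i)`
#'   (returned unchanged).
#' @return A vectorised-in-`i` function of `(n, i)`.
#' @export
alpha_function <- function(name) {
  if (is.function(name)) return(name)
  switch(match.arg(name, c("indicator", "linear", "exponential")),
    indicator   = function(n, i) as.numeric(i == n),
    linear      = function(n, i) 1 / (n + 1 - i),
    exponential = function(n, i) 2^(i - n)
  )
}

#' Check the monotonicity conditions on a stress weight function
#'
#' Verifies by enumeration that `alpha(n + 1, i + 1) <= alpha(n, i)` and
#' `alpha(n + 1, i) <= alpha(n, i)` for all `1 <= i <= n <= n_max`: when the
#' family grows by one member, an author's weight may never increase,
#' whether or not the author belongs to the new member.  Weights satisfying
#' both conditions make [stress_alpha()] monotone under multiset inclusion,
#' which is what allows it to drive a bottom-up merge procedure.
#'
#' @inheritParams stress_alpha
#' @param n_max Largest family size to check (at least 2).
#' @return `TRUE` if both inequalities hold throughout, else `FALSE`.
#' @examples
#' check_alpha_monotone("exponential", 10)  # TRUE
#' check_alpha_monotone(function(n, i) i / n, 3)  # FALSE
#' @export
check_alpha_monotone <- function(alpha, n_max = 10L) {
  stopifnot(n_max >= 2)
  alpha <- alpha_function(alpha)
  for (n in seq_len(n_max - 1L)) {
    for (i in seq_len(n)) {
      if (alpha(n + 1L, i + 1L) > alpha(n, i) + 1e-12) return(FALSE)
      if (alpha(n + 1L, i) > alpha(n, i) + 1e-12) return(FALSE)
    }
  }
  TRUE
}

# Validate a family of author sets: non-empty list, non-empty union.
check_family <- function(sets) {
  if (!is.list(sets)) sets <- list(sets)
  if (length(sets) == 0L) {
    stop_citesum("a family of author sets must have at least one member",
                 "citesum_empty_family")
  }
  sets <- lapply(sets, as_author_set)
  if (sum(lengths(sets)) == 0L) {
    stop_citesum("stress is undefined for a family whose union is empty",
                 "citesum_empty_union")
  }
  sets
}
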