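#' Pairwise grouping of the six post-neurons
#'
#' The six post-neurons are paired into three groups, each comparing two of
#' the three vowels: /a/ vs /i/, /a/ vs /u/ and /i/ vs /u/ by default. Every
#' class is represented in exactly two groups, so a correctly recognized
#' code fires exactly two of the six neurons.
#'
#' @param groups list of 3 pairs; each pair is a named integer vector of two
#'   neuron indices (1-based), names giving the class each neuron represents.
#' @return An object of class \code{pair_grouping}.
#' @examples
#' g <- pair_grouping()
#' label_vector("a", g)  # 1 0 1 0 0 0
#' @export
pair_grouping <- function(groups = list(c(a = 1L, i = 2L),
                                        c(a = 3L, u = 4L),
                                        c(i = 5L, u = 6L))) {
  idx <- unlist(groups, use.names = FALSE)
  cls <- unlist(lapply(groups, names))
  if (anyDuplicated(idx)) stop("neuron indices must be distinct")
  tab <- table(cls)
  if (any(tab != 2)) stop("each class must appear in exactly 2 groups")
  structure(list(groups = groups,
                 n_neurons = max(idx),
                 classes = sort(unique(cls))),
            class = "pair_grouping")
}

#' Desired-output label vector for a class
#'
#' The label data predetermine which neurons should fire: exactly the two
#' neurons representing \code{class} in its two groups.
#'
#' @param class class label (one of the grouping's classes).
#' @param grouping a \code{\link{pair_grouping}}.
#' @return Integer 0/1 vector, length = number of post-neurons, with exactly
#'   two ones.
#' @export
label_vector <- function(class, grouping = pair_grouping()) {
  if (!class %in% grouping$classes) stop("unknown class: ", class)
  lab <- integer(grouping$n_neurons)
  for (g in grouping$groups) {
    hit <- names(g) == class
    if (any(hit)) lab[g[hit]] <- 1L
  }
  lab
}

#' Rival rows of a class (targets of the depression phase)
#'
#' Within each group containing \code{class}, the other member is the rival
#' that must not fire first; depression targets those rows at the code's
#' active bits.
#'
#' @inheritParams label_vector
#' @return Integer 0/1 vector marking the rival neurons.
#' @export
rival_vector <- function(class, grouping = pair_grouping()) {
  if (!class %in% grouping$classes) stop("unknown class: ", class)
  riv <- integer(grouping$n_neurons)
  for (g in grouping$groups) {
    if (class %in% names(g)) riv[g[names(g) != class]] <- 1L
  }
  riv
}

#' First-to-fire classification over pairwise groups
#'
#' Per group, the member with the earlier fire time wins (a firing member
#' beats a non-firing one; a tie or no fire at all makes the group abstain).
#' The output is the class winning at least two of the three groups; if no
#' class reaches two wins (all groups abstain, or a cyclic outcome gives one
#' win each), the classifier abstains.
#'
#' @param fires numeric vector of per-neuron fire times (seconds), \code{NA}
#'   for neurons that did not fire.
#' @param grouping a \code{\link{pair_grouping}}.
#' @return A single string: the winning class, or \code{"abstain"}.
#' @export
classify <- function(fires, grouping = pair_grouping()) {
  if (length(fires) < grouping$n_neurons) stop("fire record too short")
  wins <- character(0)
  for (g in grouping$groups) {
    t1 <- fires[g[1]]; t2 <- fires[g[2]]
    w <- if (is.na(t1) && is.na(t2)) NA_character_
         else if (is.na(t2)) names(g)[1]
         else if (is.na(t1)) names(g)[2]
         else if (t1 < t2) names(g)[1]
         else if (t2 < t1) names(g)[2]
         else NA_character_   # exact tie: group abstains
    wins <- c(wins, w)
  }
  tab <- table(wins[!is.na(wins)])
  if (length(tab) && max(tab) >= 2) names(tab)[which.max(tab)] else "abstain"
}

#' Per-group winners of a fire record
#'
#' @inheritParams classify
#' @return Character vector, one entry per group: winning class or \code{NA}
#'   (abstention).
#' @export
group_winners <- function(fires, grouping = pair_grouping()) {
  vapply(grouping$groups, function(g) {
    t1 <- fires[g[1]]; t2 <- fires[g[2]]
    if (is.na(t1) && is.na(t2)) return(NA_character_)
    if (is.na(t2)) return(names(g)[1])
    if (is.na(t1)) return(names(g)[2])
    if (t1 < t2) names(g)[1] else if (t2 < t1) names(g)[2] else NA_character_
  }, character(1))
}
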