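#' Partition EGGs into pre-connected components
#'
#' Optional acceleration step run before the similarity computation: EGGs
#' are gathered into rough groups so that the similarity matrix and the
#' complete-linkage clustering run per component. An EGG belongs with a
#' component when its (family, label) set shares at least
#' `min_nb_linclusters` entries with the component's label union; merging is
#' repeated until a fixpoint, so the result is the monotone closure and does
#' not depend on EGG order. Note that two EGGs can have a high Dice value
#' yet share fewer than `min_nb_linclusters` labels, so clustering per
#' component is not guaranteed to equal the unpartitioned run; the pipeline
#' can report any divergence (see [mps_run()]).
#'
#' @param eggs an `egg_set` from [collapse_to_eggs()].
#' @param min_nb_linclusters minimum number of shared (family, label)
#'   entries for an EGG to join a component (>= 1).
#' @return a list of class `pre_components`: `egg2component` (integer vector
#'   over EGGs), `components` (list of EGG-id vectors), `label_union`
#'   (list of token vectors per component).
#' @export
build_components <- function(eggs, min_nb_linclusters = 2L) {
  stopifnot(inherits(eggs, "egg_set"), min_nb_linclusters >= 1L)
  E <- nrow(eggs$labels)
  tokens <- lapply(seq_len(E), function(i) egg_label_tokens(eggs$labels[i, ]))
  comp <- seq_len(E)
  repeat {
    changed <- FALSE
    unions <- lapply(split(seq_len(E), comp), function(idx)
      unique(unlist(tokens[idx], use.names = FALSE)))
    for (e in seq_len(E)) {
      own <- as.character(comp[e])
      shared <- vapply(unions, function(u)
        sum(tokens[[e]] %in% u), integer(1))
      hits <- names(unions)[shared >= min_nb_linclusters]
      hits <- setdiff(hits, own)
      if (length(hits)) {
        merged <- as.integer(c(own, hits))
        new_id <- min(merged)
        comp[comp %in% merged] <- new_id
        unions <- lapply(split(seq_len(E), comp), function(idx)
          unique(unlist(tokens[idx], use.names = FALSE)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  finalize_components(comp, tokens)
}

#' Bypass pre-connection
#'
#' Puts every EGG into a single component, the behaviour of a run without
#' the optional pre-connection step.
#'
#' @param eggs an `egg_set`.
#' @return a `pre_components` object with one component (empty for an empty
#'   `egg_set`).
#' @export
bypass_components <- function(eggs) {
  stopifnot(inherits(eggs, "egg_set"))
  E <- nrow(eggs$labels)
  tokens <- lapply(seq_len(E), function(i) egg_label_tokens(eggs$labels[i, ]))
  finalize_components(rep(1L, E), tokens)
}

# Renumber components 1..k by smallest member EGG id.
finalize_components <- function(comp, tokens) {
  if (length(comp) == 0L)
    return(structure(list(egg2component = integer(0), components = list(),
                          label_union = list()),
                     class = "pre_components"))
  firsts <- sort(unique(comp))
  renum <- stats::setNames(seq_along(firsts), firsts)
  comp <- unname(renum[as.character(comp)])
  components <- unname(split(seq_along(comp), comp))
  label_union <- lapply(components, function(idx)
    unique(unlist(tokens[idx], use.names = FALSE)))
  structure(list(egg2component = comp, components = components,
                 label_union = label_union),
            class = "pre_components")
}
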