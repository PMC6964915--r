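#' Define the set of conditioned stimuli for an experiment
#'
#' A cue set lists the elemental conditioned stimuli (CSs) of an experiment
#' and, optionally, compound stimuli formed by presenting several elements
#' jointly (e.g. the compound `AB` used in blocking designs). The
#' *presentable* stimuli -- the states of the trial-generating Markov chain --
#' are the elements followed by the compounds.
#'
#' Compound presentation is a single draw of the compound label: a trial shows
#' either `A`, `B`, or `AB`, never independently sampled elements.
#'
#' @param elements character vector of unique elemental cue labels.
#' @param compounds list of character vectors, each a subset of `elements`
#'   with at least two members. A compound's label is the concatenation of its
#'   members (so `c("A","B")` becomes `"AB"`).
#'
#' @return An object of class `cue_set` with fields `elements`, `compounds`
#'   (named list of member vectors) and `presentable` (character vector).
#' @examples
#' cue_set(c("A", "B"), compounds = list(c("A", "B")))
#' @export
cue_set <- function(elements, compounds = list()) {
  elements <- as.character(elements)
  if (anyDuplicated(elements)) stop("cue labels must be unique")
  if (length(elements) < 1L) stop("at least one elemental cue is required")
  compounds <- lapply(compounds, as.character)
  for (cmp in compounds) {
    if (length(cmp) < 2L) stop("a compound must contain at least two elements")
    if (!all(cmp %in% elements)) stop("compound members must be elemental cues")
    if (anyDuplicated(cmp)) stop("compound members must be distinct")
  }
  labels <- vapply(compounds, paste0, "", collapse = "")
  if (anyDuplicated(c(elements, labels))) stop("stimulus labels must be unique")
  names(compounds) <- labels
  structure(
    list(elements = elements, compounds = compounds,
         presentable = c(elements, labels)),
    class = "cue_set"
  )
}

#' @export
print.cue_set <- function(x, ...) {
  cat("<cue_set> elements:", paste(x$elements, collapse = ", "))
  if (length(x$compounds))
    cat(" | compounds:", paste(names(x$compounds), collapse = ", "))
  cat("\n")
  invisible(x)
}

# 0/1 membership of each presentable stimulus over the elemental cues,
# one row per presentable label.
cue_membership <- function(cues) {
  m <- matrix(0, nrow = length(cues$presentable), ncol = length(cues$elements),
              dimnames = list(cues$presentable, cues$elements))
  for (el in cues$elements) m[el, el] <- 1
  for (lab in names(cues$compounds)) m[lab, cues$compounds[[lab]]] <- 1
  m
}
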