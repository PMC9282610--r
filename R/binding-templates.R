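# Structure templates for the time-based binding simulation.
#
# A template is a small DAG of nodes in four layers: S (syllable inputs),
# PO (propositional objects), RB (role-filler bindings) and P (propositions).
# Non-S nodes integrate their children through a causal boxcar whose length
# depends on how many children they bind (30 ms for one child, 250 ms for
# two), then refine the result with a zero-phase low-pass whose cutoff
# encodes the layer (PO 50 Hz, RB 35 Hz, P 20 Hz).

LAYER_CUTOFFS <- c(PO = 50, RB = 35, P = 20)

new_structure_template <- function(condition, nodes) {
  tpl <- list(condition = condition, nodes = nodes)
  class(tpl) <- "structure_template"
  validate_template(tpl)
  tpl
}

#' Binding-network template for the phrase condition
#'
#' Four syllable inputs feed three PO units (the middle two syllables bind
#' into one PO), which bind into two RB units and a single determiner-phrase
#' proposition.
#'
#' @return A `structure_template` object.
#' @export
phrase_template <- function() {
  new_structure_template("phrase", tibble::tibble(
    id       = c("S1", "S2", "S3", "S4", "PO1", "PO2", "PO3", "RB1", "RB2", "P_DP"),
    layer    = c("S", "S", "S", "S", "PO", "PO", "PO", "RB", "RB", "P"),
    children = list(
      character(), character(), character(), character(),
      "S1", c("S2", "S3"), "S4",
      c("PO2", "PO3"), "PO1",
      c("RB1", "RB2")
    )
  ))
}

#' Binding-network template for the sentence condition
#'
#' Each syllable feeds its own PO unit; POs bind pairwise into two RBs; a
#' determiner-phrase proposition embeds under a top-level sentence
#' proposition. The sentence network has one more non-S node than the phrase
#' network, expressing the extra constituent.
#'
#' @return A `structure_template` object.
#' @export
sentence_template <- function() {
  new_structure_template("sentence", tibble::tibble(
    id       = c("S1", "S2", "S3", "S4", "PO1", "PO2", "PO3", "PO4",
                 "RB1", "RB2", "P_DP", "P_s"),
    layer    = c("S", "S", "S", "S", "PO", "PO", "PO", "PO",
                 "RB", "RB", "P", "P"),
    children = list(
      character(), character(), character(), character(),
      "S1", "S2", "S3", "S4",
      c("PO1", "PO2"), c("PO3", "PO4"),
      "RB1", c("P_DP", "RB2")
    )
  ))
}

#' Read a binding template from a YAML file
#'
#' The file maps node ids to a `layer` and a `children` list, plus a
#' top-level `condition`; see `system.file("extdata", "phrase_template.yaml",
#' package = "oscbind")`.
#'
#' @param path Path to a YAML template description.
#' @return A `structure_template` object.
#' @export
read_template <- function(path) {
  spec <- yaml::read_yaml(path)
  ids <- names(spec$nodes)
  new_structure_template(
    spec$condition,
    tibble::tibble(
      id = ids,
      layer = unname(vapply(spec$nodes, function(n) n$layer, character(1))),
      children = unname(lapply(spec$nodes, function(n) as.character(n$children %||% character())))
    )
  )
}

# Boxcar length rule: 30 ms for one child, 250 ms for two.
kernel_ms_for <- function(n_children) {
  if (n_children == 1) 30 else if (n_children == 2) 250 else
    abort("non-S nodes must have 1 or 2 children")
}

validate_template <- function(tpl) {
  nodes <- tpl$nodes
  if (anyDuplicated(nodes$id)) abort("duplicate node ids")
  s_nodes <- nodes$id[nodes$layer == "S"]
  if (length(s_nodes) != 4) abort("template must have exactly 4 S-layer inputs")
  nch <- lengths(nodes$children)
  if (any(nch[nodes$layer == "S"] != 0)) abort("S nodes cannot have children")
  if (any(!nch[nodes$layer != "S"] %in% 1:2)) {
    abort("non-S nodes must have 1 or 2 children")
  }
  unknown <- setdiff(unlist(nodes$children), nodes$id)
  if (length(unknown)) abort(paste("unknown child id:", unknown[1]))
  if (!all(nodes$layer %in% c("S", "PO", "RB", "P"))) abort("unknown layer")
  topological_order(tpl) # errors on cycles
  # every non-S node reachable from the root
  roots <- nodes$id[nodes$layer == "P" & !nodes$id %in% unlist(nodes$children)]
  if (length(roots) != 1) abort("template must have exactly one P-layer root")
  reach <- character()
  stack <- roots
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% reach) next
    reach <- c(reach, cur)
    stack <- c(stack, nodes$children[[match(cur, nodes$id)]])
  }
  if (!all(nodes$id %in% reach)) abort("unreachable nodes in template")
  invisible(tpl)
}

# Children-before-parents ordering of non-S nodes; errors on cycles.
topological_order <- function(tpl) {
  nodes <- tpl$nodes
  done <- nodes$id[nodes$layer == "S"]
  pending <- nodes$id[nodes$layer != "S"]
  order <- character()
  while (length(pending)) {
    ready <- pending[vapply(pending, function(id) {
      all(nodes$children[[match(id, nodes$id)]] %in% done)
    }, logical(1))]
    if (!length(ready)) abort("template contains a cycle")
    order <- c(order, ready)
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  order
}

#' @export
print.structure_template <- function(x, ...) {
  cat("<structure_template: ", x$condition, ">\n", sep = "")
  n <- x$nodes
  for (i in seq_len(nrow(n))) {
    cat(sprintf(
      "  %-5s [%s]%s\n", n$id[i], n$layer[i],
      if (length(n$children[[i]])) paste0(" <- ", paste(n$children[[i]], collapse = " + ")) else ""
    ))
  }
  invisible(x)
}

#' Summarise a binding template as a tibble
#'
#' One row per node with layer, children, boxcar kernel length and low-pass
#' cutoff.
#'
#' @param x A `structure_template`.
#' @param ... Unused.
#' @export
tidy.structure_template <- function(x, ...) {
  n <- x$nodes
  tibble::tibble(
    condition = x$condition,
    id = n$id,
    layer = n$layer,
    n_children = lengths(n$children),
    kernel_ms = vapply(seq_len(nrow(n)), function(i) {
      if (n$layer[i] == "S") NA_real_ else kernel_ms_for(length(n$children[[i]]))
    }, numeric(1)),
    cutoff_hz = unname(LAYER_CUTOFFS[n$layer])
  )
}
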