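# Three-step propagation through a binding template:
#  1. time-based binding — causal boxcar (moving average) over the summed
#     child activations, window 30 ms (one child) or 250 ms (two children);
#  2. refinement — zero-phase FIR low-pass at the layer cutoff
#     (PO 50 Hz, RB 35 Hz, P 20 Hz);
#  3. amplitude normalisation — pointwise division by the maximum
#     (skipped for all-zero signals).

#' Propagate a drive through a binding template
#'
#' Computes, in topological order, the activation of every non-S node of the
#' template from the four S-unit drive sequences of one pair.
#'
#' @param template A `structure_template` (see [phrase_template()]).
#' @param drive A `drive_set` from [gen_drive()].
#' @param pair Index of the drive pair to propagate.
#' @return A named list of numeric activation vectors, one per node
#'   (S nodes are the raw drive sequences), with attributes `fs` and
#'   `condition`.
#' @export
propagate <- function(template, drive, pair = 1) {
  stopifnot(inherits(template, "structure_template"), inherits(drive, "drive_set"))
  fs <- drive$fs
  nodes <- template$nodes
  acts <- list()
  for (k in 1:4) acts[[paste0("S", k)]] <- drive$sequences[pair, k, ]
  for (id in topological_order(template)) {
    i <- match(id, nodes$id)
    ch <- nodes$children[[i]]
    input <- Reduce(`+`, acts[ch])
    width <- max(1L, round(kernel_ms_for(length(ch)) / 1000 * fs))
    y <- causal_moving_average(input, width)
    if (any(y != 0)) {
      y <- lowpass_zero_phase(y, fs, LAYER_CUTOFFS[[nodes$layer[i]]])
    }
    acts[[id]] <- peak_normalize(y)
  }
  attr(acts, "fs") <- fs
  attr(acts, "condition") <- template$condition
  acts
}

# Propagate all pairs, returning matrices time x pair for each node.
propagate_all <- function(template, drive) {
  node_ids <- template$nodes$id
  n_time <- dim(drive$sequences)[3]
  out <- lapply(node_ids, function(id) matrix(0, n_time, drive$n_pairs))
  names(out) <- node_ids
  for (p in seq_len(drive$n_pairs)) {
    acts <- propagate(template, drive, pair = p)
    for (id in node_ids) out[[id]][, p] <- acts[[id]]
  }
  attr(out, "fs") <- drive$fs
  attr(out, "condition") <- template$condition
  attr(out, "layers") <- stats::setNames(template$nodes$layer, node_ids)
  out
}
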