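# Nonparametric cluster-based permutation test over channel x frequency x
# time data with spatial (channel neighbour) and temporal-spectral
# (consecutive bin) adjacency. Paired design: per-bin dependent t tests,
# entry threshold p < alpha_entry (two-sided), connected components formed
# separately for positive and negative t, cluster mass = sum of t values,
# null = maximum absolute cluster mass under random within-subject
# condition flips.

#' Channel adjacency from 2-D montage coordinates
#'
#' Each channel is linked to its `k` nearest neighbours (symmetrised,
#' no self-neighbours).
#'
#' @param xy Channel x 2 coordinate matrix.
#' @param k Nearest neighbours per channel (default 4).
#' @return List of integer neighbour vectors, one per channel.
#' @export
channel_adjacency <- function(xy, k = 4) {
  n <- nrow(xy)
  k <- min(k, n - 1)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  # symmetrise
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!i %in% nb[[j]]) nb[[j]] <- sort(c(nb[[j]], i))
    }
  }
  nb
}

# flat neighbour list over the channel x freq x time grid
grid_neighbors <- function(n_ch, n_freq, n_time, chan_nb) {
  idx <- function(c, f, t) c + n_ch * ((f - 1) + n_freq * (t - 1))
  nbs <- vector("list", n_ch * n_freq * n_time)
  for (t in seq_len(n_time)) {
    for (f in seq_len(n_freq)) {
      for (c in seq_len(n_ch)) {
        me <- idx(c, f, t)
        out <- integer()
        if (length(chan_nb)) out <- c(out, idx(chan_nb[[c]], f, t))
        if (f > 1) out <- c(out, idx(c, f - 1, t))
        if (f < n_freq) out <- c(out, idx(c, f + 1, t))
        if (t > 1) out <- c(out, idx(c, f, t - 1))
        if (t < n_time) out <- c(out, idx(c, f, t + 1))
        nbs[[me]] <- out
      }
    }
  }
  nbs
}

# connected components of `members` (integer bin ids) under the
# precomputed neighbour lists; iterative flood fill
flood_components <- function(members, neighbors) {
  if (!length(members)) return(list())
  inset <- logical(length(neighbors))
  inset[members] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (m in members) {
    if (seen[m]) next
    comp <- integer()
    stack <- m
    seen[m] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      for (nb in neighbors[[cur]]) {
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# max |cluster mass| over sign-split components of the t map
max_cluster_mass <- function(tvals, keep_pos, keep_neg, neighbors) {
  m <- 0
  for (comps in list(flood_components(which(keep_pos), neighbors),
                     flood_components(which(keep_neg), neighbors))) {
    for (cmp in comps) m <- max(m, abs(sum(tvals[cmp])))
  }
  m
}

#' Cluster-based permutation test for paired multichannel data
#'
#' @param cond_a,cond_b Subject x channel x freq x time arrays (paired,
#'   equal shapes, >= 3 subjects).
#' @param chan_nb Channel neighbour list (e.g. [channel_adjacency()]);
#'   `NULL` for no spatial adjacency (channels independent).
#' @param alpha_entry Two-sided per-bin entry threshold (default 0.05).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return A `cluster_result`: list with `clusters` tibble (id, sign, mass,
#'   n_bins, p), `membership` (list of bin-index vectors), `t_map`
#'   (channel x freq x time), `overall_p` (smallest cluster p, 1 when no
#'   cluster), `n_perm`.
#' @export
cluster_test <- function(cond_a, cond_b, chan_nb = NULL, alpha_entry = 0.05,
                         n_perm = 1000, seed = 1) {
  if (!identical(dim(cond_a), dim(cond_b))) abort("condition shapes differ")
  d <- dim(cond_a)
  if (length(d) != 4) abort("need subject x channel x freq x time arrays")
  n_sub <- d[1]
  if (n_sub < 3) abort("need at least 3 subjects")
  n_bins <- prod(d[2:4])
  D <- matrix(aperm(cond_a - cond_b, c(1, 2, 3, 4)), n_sub, n_bins)
  ssq <- colSums(D^2)
  t_of_signs <- function(s) {
    mu <- as.vector(s %*% D) / n_sub # sign flips leave squares unchanged
    v <- (ssq / n_sub - mu^2) * n_sub / (n_sub - 1)
    t <- mu / sqrt(v / n_sub)
    t[v == 0] <- 0
    t
  }
  tcrit <- qt(1 - alpha_entry / 2, df = n_sub - 1)
  t_obs <- t_of_signs(matrix(1, 1, n_sub))
  neighbors <- grid_neighbors(d[2], d[3], d[4], chan_nb %||% lapply(seq_len(d[2]), function(i) integer()))
  pos <- t_obs > tcrit
  neg <- t_obs < -tcrit
  comps <- c(lapply(flood_components(which(pos), neighbors), function(x) list(x, 1)),
             lapply(flood_components(which(neg), neighbors), function(x) list(x, -1)))
  set.seed(substream_seed(seed, "cluster"))
  null_max <- vapply(seq_len(n_perm), function(p) {
    s <- matrix(sample(c(-1, 1), n_sub, replace = TRUE), 1, n_sub)
    tp <- t_of_signs(s)
    max_cluster_mass(tp, tp > tcrit, tp < -tcrit, neighbors)
  }, numeric(1))
  clusters <- dplyr::bind_rows(lapply(seq_along(comps), function(i) {
    bins <- comps[[i]][[1]]
    mass <- sum(t_obs[bins])
    tibble::tibble(
      id = i, sign = comps[[i]][[2]], mass = mass, n_bins = length(bins),
      p = (sum(null_max >= abs(mass)) + 1) / (n_perm + 1)
    )
  }))
  structure(
    list(
      clusters = clusters,
      membership = lapply(comps, `[[`, 1),
      t_map = array(t_obs, d[2:4]),
      overall_p = if (nrow(clusters)) min(clusters$p) else 1,
      n_perm = n_perm, dims = d[2:4]
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), overall p = %.4g>\n",
              nrow(x$clusters), x$overall_p))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Cluster table of a cluster permutation test
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters), overall_p = x$overall_p,
                 n_perm = x$n_perm)
}

#' Convert flat bin indices of a cluster to channel/freq/time coordinates
#'
#' @param result A `cluster_result`.
#' @param id Cluster id.
#' @return Tibble with channel, freq_idx, time_idx.
#' @export
cluster_bins <- function(result, id) {
  stopifnot(inherits(result, "cluster_result"))
  bins <- result$membership[[id]]
  d <- result$dims
  b0 <- bins - 1
  tibble::tibble(
    channel = b0 %% d[1] + 1,
    freq_idx = (b0 %/% d[1]) %% d[2] + 1,
    time_idx = b0 %/% (d[1] * d[2]) + 1
  )
}
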