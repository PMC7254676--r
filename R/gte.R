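#' Generalized Transfer Entropy scores between spike trains
#'
#' Plug-in transfer entropy in bits between every ordered pair of active
#' neurons, computed on the binary spike trains themselves. For source `I`
#' and target `J` with Markov order `k`, the score is
#' \deqn{GTE(I \to J) = \sum p(j_{t+1}, j_t^{(k)}, i_t^{(k)}, i_{t+1})
#'   \log_2 \frac{p(j_{t+1} \mid j_t^{(k)}, i_t^{(k)}, i_{t+1})}
#'               {p(j_{t+1} \mid j_t^{(k)})}}
#' where \eqn{j_t^{(k)}} is the k-frame past and the same-frame source state
#' \eqn{i_{t+1}} enters the conditioning set when `instant_feedback` is on.
#' Probabilities are estimated by counting over all frames; states with zero
#' count contribute zero to the sum.
#'
#' Inference is refused (status `"refused"`, no scores) when the active set
#' has `min_active` or fewer neurons, mirroring the analysis rule that
#' effective connectivity is only estimated on recordings with more than 25
#' active neurons.
#'
#' @param raster A [spike_raster()].
#' @param active_ids Neuron ids to analyse (default: neurons with >= 2
#'   spikes).
#' @param k Markov order (past frames conditioned on).
#' @param instant_feedback Include the source's same-frame state.
#' @param min_active Refusal threshold on the active-set size.
#' @return A list with `status` (`"ok"`/`"refused"`), `n_active`,
#'   `active_ids` and, when ok, `scores` (n x n matrix in bits, `NA`
#'   diagonal; rows = source, columns = target).
#' @export
compute_gte_scores <- function(raster, active_ids = NULL, k = 2,
                               instant_feedback = TRUE, min_active = 25) {
  if (is.null(active_ids))
    active_ids <- which(spike_counts(raster) >= 2L)
  n <- length(active_ids)
  if (n <= min_active) {
    return(list(status = "refused", n_active = n, active_ids = active_ids,
                scores = NULL,
                reason = sprintf(
                  "network inference requires more than %d active neurons (%d found)",
                  min_active, n)))
  }
  Tn <- raster$n_frames
  if (Tn <= k + 1L) stop("raster too short for the requested Markov order")
  X <- matrix(0L, n, Tn)
  ev <- raster$events
  sel <- ev$neuron %in% active_ids
  X[cbind(match(ev$neuron[sel], active_ids), ev$frame[sel])] <- 1L

  u <- (k + 1L):Tn          # predicted frames
  m <- length(u)
  jnext <- X[, u, drop = FALSE]
  past <- matrix(0L, n, m)
  for (l in seq_len(k)) past <- past + X[, u - l, drop = FALSE] * 2L^(l - 1L)
  np <- 2L^k
  # state code layout: jnext + 2*jpast + 2*np*ipast (+ 2*np*np*iinst)
  nstates <- as.integer(2L * np * np * (if (instant_feedback) 2L else 1L))
  s <- 0:(nstates - 1L)
  s_jn <- s %% 2L
  s_jp <- (s %/% 2L) %% np
  s_ip <- (s %/% (2L * np)) %% np
  s_ii <- s %/% (2L * np * np)
  cond_id <- s_jp + np * s_ip + np * np * s_ii # conditioning: jpast,ipast,(iinst)
  jp_id <- s_jp                                # jpast alone
  jn_id <- s_jn + 2L * s_jp                    # (jnext, jpast)

  # frames where a neuron contributes any nonzero state bit; outside the
  # union of two neurons' lists the joint state is all-zero, so its count
  # is recovered from the frame total without scanning
  nzl <- lapply(seq_len(n), function(i)
    which(past[i, ] > 0L | jnext[i, ] > 0L))

  scores <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    base_j <- jnext[j, ] + 2L * past[j, ]
    nzj <- nzl[[j]]
    for (i in seq_len(n)) {
      if (i == j) next
      idx <- sort.int(unique(c(nzj, nzl[[i]])))
      v <- base_j[idx] + (2L * np) * past[i, idx]
      if (instant_feedback) v <- v + (2L * np * np) * jnext[i, idx]
      cnt <- tabulate(v + 1L, nbins = nstates)
      cnt[1L] <- cnt[1L] + (m - length(idx))
      # marginal counts; group g sits at row g+1 (all groups 0..G-1 present)
      c_cond <- rowsum(cnt, cond_id)
      c_jp <- rowsum(cnt, jp_id)
      c_jn <- rowsum(cnt, jn_id)
      nz <- which(cnt > 0L)
      cc <- cnt[nz]
      scores[i, j] <- sum(cc / m *
        log2((cc * c_jp[jp_id[nz] + 1L]) /
               (c_cond[cond_id[nz] + 1L] * c_jn[jn_id[nz] + 1L])))
    }
  }
  list(status = "ok", n_active = n, active_ids = active_ids, scores = scores)
}

#' Threshold GTE scores into a significant-edge network
#'
#' For each candidate connection `i -> j` the null set is the joint
#' distribution of all scores into `j` and all scores out of `i` (every
#' `x -> j` and `i -> y`); the edge is significant when its score strictly
#' exceeds the mean plus two standard deviations of that set. A degenerate
#' null (zero spread) yields no edges.
#'
#' @param gte A [compute_gte_scores()] result (status `"ok"`).
#' @param n_sd Number of standard deviations above the null mean.
#' @return An object of class `effective_network`: list with `scores`,
#'   `adjacency` (binary, rows = source), `n_active`, `active_ids`,
#'   `status`.
#' @export
threshold_network <- function(gte, n_sd = 2) {
  if (!identical(gte$status, "ok"))
    stop("cannot threshold a refused inference: ", gte$reason %||% "")
  s <- gte$scores
  n <- nrow(s)
  sc <- s; sc[is.na(sc)] <- 0
  col_sum <- colSums(sc);  col_sq <- colSums(sc^2)
  row_sum <- rowSums(sc);  row_sq <- rowSums(sc^2)
  # union of column j (n-1 values) and row i (n-1 values), counting the
  # candidate score itself once: 2n - 3 values
  nu <- 2L * n - 3L
  tot <- outer(row_sum, col_sum, "+") - sc
  tot2 <- outer(row_sq, col_sq, "+") - sc^2
  mu <- tot / nu
  va <- (tot2 - nu * mu^2) / (nu - 1L)
  va[va < 0] <- 0
  adj <- (s > mu + n_sd * sqrt(va)) * 1L
  adj[is.na(adj)] <- 0L
  diag(adj) <- 0L
  structure(list(scores = s, adjacency = adj, n_active = n,
                 active_ids = gte$active_ids, status = "ok"),
            class = "effective_network")
}

#' @export
print.effective_network <- function(x, ...) {
  cat(sprintf("Effective network: %d neurons, %d significant edges\n",
              x$n_active, sum(x$adjacency)))
  invisible(x)
}

#' Infer the effective network of a recording
#'
#' Convenience wrapper: [compute_gte_scores()] followed by
#' [threshold_network()]. A refused inference (too few active neurons) is
#' returned as a status object rather than an error, so pipelines can log it.
#'
#' @inheritParams compute_gte_scores
#' @param n_sd Significance threshold in null standard deviations.
#' @return An `effective_network`, or a refusal status list.
#' @export
infer_effective_network <- function(raster, active_ids = NULL, k = 2,
                                    instant_feedback = TRUE, min_active = 25,
                                    n_sd = 2) {
  g <- compute_gte_scores(raster, active_ids = active_ids, k = k,
                          instant_feedback = instant_feedback,
                          min_active = min_active)
  if (!identical(g$status, "ok")) return(g)
  threshold_network(g, n_sd = n_sd)
}

#' Write an effective network as an edge list
#' @param net An `effective_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  df <- data.frame(from = net$active_ids[idx[, 1L]],
                   to = net$active_ids[idx[, 2L]],
                   score = net$scores[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
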