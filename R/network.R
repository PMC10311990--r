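#' Build a ground-truth feedforward weight vector
#'
#' `n_connected` cells of the population (drawn without replacement) receive
#' nonzero synaptic weights: `n_excitatory` of them uniform on `(0, max]`,
#' the rest uniform on `[min, 0)`; all remaining cells are exactly
#' unconnected (weight 0). Defaults follow a 200-cell population with 100
#' connected inputs at an 80:20 excitatory:inhibitory split and weights in
#' `[-8, 8]` mV.
#'
#' @param n_population population size.
#' @param n_connected number of connected inputs (default 100).
#' @param n_excitatory number of excitatory inputs among the connected ones
#'   (default 80).
#' @param weight_range numeric length-2, weight support in mV
#'   (default `c(-8, 8)`).
#' @param seed RNG seed.
#' @return Numeric weight vector of length `n_population` (mV). Roles are
#'   recoverable from the sign: positive = excitatory, negative =
#'   inhibitory, zero = unconnected.
#' @export
#' @examples
#' w <- build_feedforward_weights(200, seed = 1)
#' table(sign(w))
build_feedforward_weights <- function(n_population = 200, n_connected = 100,
                                      n_excitatory = 80,
                                      weight_range = c(-8, 8), seed = NULL) {
  if (n_connected > n_population)
    stop_field("n_connected", "exceeds n_population")
  if (n_excitatory > n_connected)
    stop_field("n_excitatory", "exceeds n_connected")
  if (length(weight_range) != 2 || weight_range[1] > 0 || weight_range[2] < 0)
    stop_field("weight_range", "must be an interval containing 0")
  with_seed(seed, {
    w <- numeric(n_population)
    if (n_connected > 0) {
      connected <- sample.int(n_population, n_connected)
      exc <- connected[seq_len(n_excitatory)]
      inh <- connected[-seq_len(n_excitatory)]
      # uniform magnitudes, open at zero so sign encodes the role exactly
      w[exc] <- runif(length(exc), 0, weight_range[2])
      w[exc][w[exc] == 0] <- weight_range[2]
      if (length(inh)) {
        w[inh] <- runif(length(inh), weight_range[1], 0)
        w[inh][w[inh] == 0] <- weight_range[1]
      }
    }
    w
  })
}

#' Build a recurrent circuit with controlled reciprocity
#'
#' Constructs a weighted digraph in which every neuron has exactly
#' `in_degree` presynaptic partners with a 4:1 excitatory:inhibitory count
#' split, no self-edges, and an expected fraction
#' `p_rec / (p_uni + p_rec)` of connected pairs being reciprocal.
#' Reciprocal-pair members draw their weight magnitudes from the same
#' uniform law as unidirectional edges and are then scaled by
#' `rec_strength_factor` (optionally clipped back into `weight_range`).
#'
#' Reciprocal pairs are realized as a random r-regular undirected graph
#' (r chosen so the edge mixture matches the target), unidirectional edges
#' by sequential in-neighbor sampling that avoids accidental mutual pairs.
#' Parameter combinations for which this is combinatorially infeasible
#' (e.g. very dense graphs with low reciprocity) raise a construction error.
#'
#' @param n_neurons circuit size.
#' @param in_degree presynaptic partners per neuron (default 120).
#' @param p_uni,p_rec unidirectional and reciprocal connection
#'   probabilities (defaults 0.13 and 0.06); only their ratio enters the
#'   construction, setting the reciprocal/unidirectional mixture.
#' @param rec_strength_factor magnitude multiplier for reciprocal-pair
#'   members (default 1.5).
#' @param ei_ratio excitatory:inhibitory presynaptic count ratio
#'   (default 4, i.e. 96 vs 24 of 120).
#' @param weight_range weight support in mV (default `c(-8, 8)`).
#' @param clip clip reciprocal magnitudes back into `weight_range` after
#'   scaling (default TRUE).
#' @param seed RNG seed.
#' @param max_tries attempts at the unidirectional phase before giving up.
#' @return An object of class `"circuit_graph"`: list with `n_neurons` and
#'   `edges` (data frame `pre`, `post`, `weight`, `kind` where `kind` is
#'   `"unidirectional"` or `"reciprocal"`).
#' @export
#' @examples
#' g <- build_recurrent_circuit(60, in_degree = 12, seed = 1)
#' table(g$edges$kind)
build_recurrent_circuit <- function(n_neurons, in_degree = 120,
                                    p_uni = 0.13, p_rec = 0.06,
                                    rec_strength_factor = 1.5,
                                    ei_ratio = 4, weight_range = c(-8, 8),
                                    clip = TRUE, seed = NULL,
                                    max_tries = 20) {
  if (in_degree >= n_neurons)
    stop_field("in_degree", "must be < n_neurons")
  if (p_uni < 0 || p_uni > 1 || p_rec < 0 || p_rec > 1)
    stop_field("p_uni", "probabilities must lie in [0, 1]")
  if (p_uni + p_rec == 0) stop_field("p_uni", "p_uni + p_rec must be > 0")
  with_seed(seed, {
    d <- as.integer(in_degree)
    n <- as.integer(n_neurons)
    if (d == n - 1L) {
      # saturated in-structure: the digraph is complete, every pair mutual
      pre <- unlist(lapply(seq_len(n), function(j) setdiff(seq_len(n), j)))
      post <- rep(seq_len(n), each = n - 1L)
      edges <- data.frame(pre = pre, post = post)
      edges$kind <- "reciprocal"
      r_edges_of <- NULL
    } else {
      # target fraction rho of connected pairs reciprocal => fraction
      # 2*rho/(1+rho) of directed edges are reciprocal-pair members
      rho <- p_rec / (p_uni + p_rec)
      r <- round(2 * rho / (1 + rho) * d)
      if (r %% 2L == 1L && (n %% 2L == 1L)) r <- r + (if (r < d) 1L else -1L)
      u <- d - r
      rec_edges <- NULL
      if (r > 0) {
        ug <- igraph::sample_k_regular(n, r)
        el <- igraph::as_edgelist(ug, names = FALSE)
        rec_edges <- data.frame(pre = c(el[, 1], el[, 2]),
                                post = c(el[, 2], el[, 1]),
                                kind = "reciprocal")
      }
      uni_edges <- NULL
      if (u > 0) {
        partners <- vector("list", n)
        if (r > 0) {
          partners <- split(rec_edges$pre, rec_edges$post)
          partners <- lapply(seq_len(n), function(j) {
            p <- partners[[as.character(j)]]
            if (is.null(p)) integer() else p
          })
        } else partners <- rep(list(integer()), n)
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          out_to <- rep(list(integer()), n)  # j -> targets of j's uni edges
          pre_l <- vector("list", n)
          ok <- TRUE
          for (j in sample.int(n, n)) {
            cand <- setdiff(seq_len(n), c(j, partners[[j]], out_to[[j]]))
            if (length(cand) < u) { ok <- FALSE; break }
            pick <- if (length(cand) == u) cand else sample(cand, u)
            pre_l[[j]] <- pick
            for (i in pick) out_to[[i]] <- c(out_to[[i]], j)
          }
          if (ok) break
        }
        if (!ok)
          stop("circuit construction infeasible: cannot place ",
               "unidirectional edges without creating reciprocal pairs; ",
               "lower in_degree or raise n_neurons/p_rec", call. = FALSE)
        uni_edges <- data.frame(pre = unlist(pre_l),
                                post = rep(seq_len(n),
                                           vapply(pre_l, length, 1L)),
                                kind = "unidirectional")
      }
      edges <- rbind(rec_edges, uni_edges)
    }
    # signs: per postsynaptic neuron, E:I count split of in-edges
    n_exc <- round(d * ei_ratio / (ei_ratio + 1))
    ord <- order(edges$post)
    edges <- edges[ord, ]
    sign_of <- unlist(lapply(seq_len(n), function(j) {
      s <- rep(-1, d)
      s[sample.int(d, n_exc)] <- 1
      s
    }))
    mag <- runif(nrow(edges), 0, weight_range[2])
    is_rec <- edges$kind == "reciprocal"
    mag[is_rec] <- mag[is_rec] * rec_strength_factor
    if (clip) mag <- pmin(mag, weight_range[2])
    edges$weight <- sign_of * mag
    edges$pre <- as.integer(edges$pre)
    edges$post <- as.integer(edges$post)
    rownames(edges) <- NULL
    structure(list(n_neurons = n, in_degree = d,
                   edges = edges[, c("pre", "post", "weight", "kind")]),
              class = "circuit_graph")
  })
}

#' @export
print.circuit_graph <- function(x, ...) {
  frac <- mean(x$edges$kind == "reciprocal")
  cat(sprintf("Circuit graph: %d neurons, in-degree %d, %d edges (%.1f%% reciprocal-members)\n",
              x$n_neurons, x$in_degree, nrow(x$edges), 100 * frac))
  invisible(x)
}

#' In-edge weights of one circuit neuron
#'
#' @param graph a [build_recurrent_circuit()] result.
#' @param post postsynaptic neuron id.
#' @return Data frame of the neuron's in-edges (`pre`, `weight`, `kind`).
#' @export
circuit_in_edges <- function(graph, post) {
  stopifnot(inherits(graph, "circuit_graph"))
  e <- graph$edges[graph$edges$post == post, c("pre", "weight", "kind")]
  rownames(e) <- NULL
  e
}

# Fraction of connected (unordered) pairs that are reciprocal.
reciprocal_pair_fraction <- function(graph) {
  e <- graph$edges
  key <- paste(pmin(e$pre, e$post), pmax(e$pre, e$post))
  tab <- table(key)
  mean(tab == 2)
}

#' Assign lognormal baseline rates to circuit neurons
#'
#' Rates are drawn from a lognormal law moment-matched to the given mean
#' and SD (both in Hz). Defaults match a typical cultured-network rate
#' distribution (mean 0.8703 Hz, SD 0.8749 Hz).
#'
#' @param graph a [build_recurrent_circuit()] result.
#' @param lognormal_mean,lognormal_sd mean and SD of the rate distribution
#'   in Hz; both must be positive.
#' @param seed RNG seed.
#' @return Numeric vector of per-neuron rates (Hz), all positive.
#' @export
assign_circuit_rates <- function(graph, lognormal_mean = 0.8703,
                                 lognormal_sd = 0.8749, seed = NULL) {
  stopifnot(inherits(graph, "circuit_graph"))
  if (lognormal_mean <= 0 || lognormal_sd <= 0)
    stop_field("lognormal_mean", "moments must be > 0")
  with_seed(seed, rlnorm_moments(graph$n_neurons, lognormal_mean,
                                 lognormal_sd))
}

#' Read and write circuit graphs as delimited edge lists
#'
#' Tab-separated text with a `#` metadata header and columns
#' `pre_id`, `post_id`, `weight`, `edge_kind` (ids 0-based on disk).
#'
#' @param graph a [build_recurrent_circuit()] result.
#' @param path file path.
#' @export
write_circuit <- function(graph, path) {
  stopifnot(inherits(graph, "circuit_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# circuit_graph n_neurons=%d in_degree=%d",
                     graph$n_neurons, graph$in_degree), con)
  writeLines("pre_id\tpost_id\tweight\tedge_kind", con)
  e <- graph$edges
  write.table(data.frame(e$pre - 1L, e$post - 1L, e$weight, e$kind),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# circuit_graph")) stop("not a circuit edge list")
  fields <- regmatches(hdr, gregexpr("[a-z_]+=[0-9]+", hdr))[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(as.integer(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  e <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(n_neurons = vals[["n_neurons"]],
                 in_degree = vals[["in_degree"]],
                 edges = data.frame(pre = e$pre_id + 1L,
                                    post = e$post_id + 1L,
                                    weight = e$weight,
                                    kind = e$edge_kind)),
            class = "circuit_graph")
}
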