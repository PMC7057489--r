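# Independent oracles and fixture builders. Nothing here calls the package's
# shortest-path or connectivity code paths.

# All-pairs shortest paths by Floyd-Warshall over the edge list.
fw_oracle <- function(node_ids, edges) {
  n <- length(node_ids)
  d <- matrix(Inf, n, n, dimnames = list(node_ids, node_ids))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]
    b <- edges$to[i]
    w <- edges$minutes[i]
    d[a, b] <- min(d[a, b], w)
    d[b, a] <- min(d[b, a], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Union-find connectivity check over an edge list.
uf_connected <- function(n_nodes, from_idx, to_idx) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(from_idx)) {
    ra <- find(from_idx[i])
    rb <- find(to_idx[i])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n_nodes), find, integer(1)))) == 1
}

# Random sparse road segments over distinct integer coordinates (so 1-mm
# rounding never merges intended nodes). Guaranteed connected via a spanning
# path plus random extra links.
random_line_features <- function(n_nodes, extra_edges = n_nodes) {
  coords <- cbind(x = sample.int(10000, n_nodes) * 100,
                  y = sample.int(10000, n_nodes) * 100)
  a <- seq_len(n_nodes - 1)
  b <- a + 1
  if (extra_edges > 0) {
    ea <- sample.int(n_nodes, extra_edges, replace = TRUE)
    eb <- sample.int(n_nodes, extra_edges, replace = TRUE)
    keep <- ea != eb
    a <- c(a, ea[keep])
    b <- c(b, eb[keep])
  }
  data.frame(
    x1 = coords[a, "x"], y1 = coords[a, "y"],
    x2 = coords[b, "x"], y2 = coords[b, "y"],
    length_km = round(stats::runif(length(a), 5, 120), 3),
    speed_kmh = round(stats::runif(length(a), 40, 110), 1))
}

# A minimal valid centres row (candidate-grade) for constructed datasets.
make_centre <- function(id, x, y, population, fp_count = 10,
                        aware = FALSE, education = FALSE,
                        telemedicine = FALSE, momentum = FALSE) {
  data.frame(community_id = id, name = id, x = x, y = y,
             population = population,
             pct_over75 = 0.1, pct_female = 0.5, pct_alone = 0.1,
             fp_count = fp_count,
             vx_1 = 0.2, vx_2 = 0.1, vx_3 = 0.1, vx_4 = 50000,
             vx_5 = 0.7, vx_6 = 0.6, vx_7 = 0.2,
             aware = aware, education = education,
             telemedicine = telemedicine, fp_adequate_override = NA,
             momentum = momentum, stringsAsFactors = FALSE)
}

make_dataset <- function(centres, blocks, network, facilities) {
  structure(list(centres = centres, blocks = blocks, network = network,
                 facilities = facilities), class = "ssm_dataset")
}

empty_blocks <- function() {
  data.frame(block_id = character(), x = numeric(), y = numeric(),
             population = numeric(), stringsAsFactors = FALSE)
}

ontario_component_cols <- c("population", "isolation", "vulnerability",
                            "readiness")
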