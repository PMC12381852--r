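# Feature construction for the GNN and the random-forest baseline.

.ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
.HYB_VOCAB <- c("SP", "SP2", "SP3", "OTHER")

# Pauling electronegativities and atomic polarizabilities (A^3) for the
# descriptor block; unknown elements fall back to carbon-like values.
.ELECTRONEG <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                 Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66)
.POLARIZ <- c(H = 0.67, B = 3.03, C = 1.76, N = 1.10, O = 0.80, F = 0.56,
              Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35)

#' Feature configuration
#'
#' Controls the composition of node/edge feature matrices and the circular
#' fingerprint used by the baseline.
#'
#' @param element_vocab Ordered element vocabulary; out-of-vocabulary
#'   elements map to the terminal `"other"` bucket.
#' @param hyb_vocab Hybridization vocabulary.
#' @param fp_radius Circular fingerprint radius in bonds (default 5).
#' @param fp_length Fingerprint length in bits (default 1024).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(element_vocab = .ELEMENT_VOCAB,
                           hyb_vocab = .HYB_VOCAB,
                           fp_radius = 5L, fp_length = 1024L) {
  stopifnot(length(element_vocab) > 0, length(hyb_vocab) > 0,
            fp_radius >= 0, fp_length > 0)
  structure(list(element_vocab = element_vocab, hyb_vocab = hyb_vocab,
                 fp_radius = as.integer(fp_radius),
                 fp_length = as.integer(fp_length)),
            class = "feature_config")
}

.one_hot <- function(values, vocab, other = NULL) {
  m <- matrix(0, length(values), length(vocab),
              dimnames = list(NULL, vocab))
  idx <- match(values, vocab)
  if (!is.null(other)) idx[is.na(idx)] <- match(other, vocab)
  stopifnot(!anyNA(idx))
  m[cbind(seq_along(values), idx)] <- 1
  m
}

.bucket04 <- function(x) {
  # one-hot buckets 0,1,2,3,4+ for counts
  v <- pmin(pmax(as.integer(x), 0L), 4L)
  m <- matrix(0, length(v), 5)
  m[cbind(seq_along(v), v + 1L)] <- 1
  colnames(m) <- paste0("n", 0:4)
  m
}

#' Node feature matrix for the GNN
#'
#' One row per heavy atom: one-hot element (with `"other"` bucket), one-hot
#' hybridization, formal charge, aromatic flag, ring flag, one-hot heavy
#' degree (0--4+), one-hot attached hydrogens (0--4+).
#'
#' @param graph An [build_graph()] `atom_graph`.
#' @param config A [feature_config()].
#' @return Numeric matrix `n_heavy x d_node`.
#' @export
node_features <- function(graph, config = feature_config()) {
  el <- graph$element
  hyb <- ifelse(graph$hyb %in% config$hyb_vocab, graph$hyb, "OTHER")
  cbind(
    .one_hot(el, config$element_vocab, other = "other"),
    .one_hot(hyb, config$hyb_vocab, other = "OTHER"),
    charge = graph$charge,
    aromatic = as.numeric(graph$aromatic),
    ring = as.numeric(graph$ring),
    .bucket04(graph$degree),
    .bucket04(graph$n_h)
  )
}

#' Edge feature matrix for the GNN
#'
#' One row per *directed* edge (each bond contributes two identical rows,
#' i->j then j->i): one-hot bond order (single/double/triple/aromatic,
#' aromatic taking precedence), conjugated flag, ring flag. The directed
#' endpoint indices are attached as attributes `src` and `dst`.
#'
#' @inheritParams node_features
#' @return Numeric matrix `n_directed_edges x d_edge` with attributes
#'   `src`, `dst` (1-based atom indices).
#' @export
edge_features <- function(graph, config = feature_config()) {
  b <- graph$bonds
  ord <- ifelse(b$aromatic, "aromatic",
                c("single", "double", "triple")[pmin(b$order, 3)])
  one <- cbind(.one_hot(ord, c("single", "double", "triple", "aromatic")),
               conjugated = as.numeric(b$conjugated),
               ring = as.numeric(b$ring))
  m <- rbind(one, one)
  attr(m, "src") <- c(b$i, b$j)
  attr(m, "dst") <- c(b$j, b$i)
  m
}

# deterministic 31-bit multiplicative string hash with memoisation
.hash_env <- new.env(parent = emptyenv())
.str_hash <- function(s) {
  cached <- .hash_env[[s]]
  if (!is.null(cached)) return(cached)
  codes <- utf8ToInt(s)
  mod <- 2147483647  # 2^31 - 1
  h <- 2166136261 %% mod
  p <- 16777619
  for (cd in codes) {
    # (h * p + cd) %% mod without exceeding 2^53: split p into 16-bit halves
    lo <- h * (p %% 65536) %% mod
    hi <- h * (p %/% 65536) %% mod
    h <- (lo + (hi * 65536) %% mod + cd) %% mod
  }
  .hash_env[[s]] <- h
  h
}

.atom_type_string <- function(graph, k) {
  paste(graph$element[k], graph$hyb[k], graph$charge[k],
        as.integer(graph$aromatic[k]), as.integer(graph$ring[k]),
        graph$degree[k], graph$n_h[k], sep = ":")
}

#' Circular atom-centered binary fingerprint
#'
#' For each depth `d` in `0..radius`, the multiset of typed atom descriptors
#' at topological distance exactly `d` from the center atom is canonicalised
#' (sorted, concatenated) and hashed, with the depth index salted into the
#' hash, onto a fixed-length bit vector. The result depends only on the
#' substructure within `radius` bonds of the atom and is invariant to atom
#' renumbering.
#'
#' @param graph An `atom_graph`.
#' @param atom_idx 1-based heavy-atom index.
#' @param radius Maximum depth in bonds (default 5).
#' @param length Fingerprint length in bits.
#' @return Integer 0/1 vector of length `length`.
#' @export
fame_fingerprint <- function(graph, atom_idx, radius = 5L, length = 1024L) {
  if (atom_idx < 1 || atom_idx > graph$n) stop("atom index out of range")
  adj <- attr(graph, "adj")
  if (is.null(adj)) adj <- .adjacency(graph)
  dist <- rep(NA_integer_, graph$n); dist[atom_idx] <- 0L
  frontier <- atom_idx
  bits <- integer(length)
  for (d in 0:radius) {
    if (!length(frontier)) break
    types <- sort(vapply(frontier, function(k) .atom_type_string(graph, k),
                         character(1)))
    key <- paste0("d", d, "|", paste(types, collapse = "|"))
    bits[(.str_hash(key) %% length) + 1L] <- 1L
    nxt <- unique(unlist(lapply(frontier, function(k) adj[[k]])))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d + 1L
    frontier <- nxt
  }
  bits
}

# Gasteiger-Marsili PEOE parameters (a, b, c) by element/hybridization;
# implicit hydrogens participate as pseudo-atoms.
.PEOE <- list(
  "H"     = c(7.17, 6.24, -0.56),
  "C.SP3" = c(7.98, 9.18, 1.88),
  "C.SP2" = c(8.79, 9.32, 1.51),
  "C.SP"  = c(10.39, 9.45, 0.73),
  "N.SP3" = c(11.54, 10.82, 1.36),
  "N.SP2" = c(12.87, 11.15, 0.85),
  "N.SP"  = c(15.68, 11.70, -0.27),
  "O.SP3" = c(14.18, 12.92, 1.39),
  "O.SP2" = c(17.07, 13.79, 0.47),
  "F"     = c(14.66, 13.85, 2.31),
  "Cl"    = c(11.00, 9.69, 1.35),
  "Br"    = c(10.08, 8.47, 1.16),
  "I"     = c(9.90, 7.96, 0.96),
  "S.SP3" = c(10.14, 9.13, 1.38),
  "S.SP2" = c(10.14, 9.13, 1.38),
  "P.SP3" = c(8.90, 8.24, 0.96)
)

.peoe_params <- function(element, hyb) {
  key <- if (element %in% c("H", "F", "Cl", "Br", "I")) element else
    paste(element, if (hyb == "OTHER") "SP3" else hyb, sep = ".")
  p <- .PEOE[[key]]
  if (is.null(p)) p <- .PEOE[[paste(element, "SP3", sep = ".")]]
  if (is.null(p)) p <- .PEOE[["C.SP3"]]
  p
}

# Partial equalization of orbital electronegativities (6 damped iterations);
# returns heavy-atom charges, with implicit H treated as explicit pseudo-atoms.
.gasteiger_charges <- function(graph) {
  n <- graph$n
  el <- graph$element; hyb <- graph$hyb
  # append pseudo hydrogens
  hn <- sum(graph$n_h)
  N <- n + hn
  elem <- c(el, rep("H", hn))
  hb <- c(hyb, rep("SP3", hn))
  edges <- cbind(graph$bonds$i, graph$bonds$j)
  if (hn > 0) {
    hosts <- rep(seq_len(n), graph$n_h)
    edges <- rbind(edges, cbind(hosts, n + seq_len(hn)))
  }
  par <- t(vapply(seq_len(N), function(k) .peoe_params(elem[k], hb[k]),
                  numeric(3)))
  chi_plus <- rowSums(par)  # electronegativity of the cation
  chi_plus[elem == "H"] <- 20.02
  q <- c(graph$charge, rep(0, hn))
  if (nrow(edges) == 0) return(q[seq_len(n)])
  damp <- 1
  for (it in 1:6) {
    damp <- damp * 0.5
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(N)
    a <- edges[, 1]; b <- edges[, 2]
    denom <- ifelse(chi[a] < chi[b], chi_plus[a], chi_plus[b])
    flow <- (chi[b] - chi[a]) / denom * damp
    for (e in seq_along(a)) {
      dq[a[e]] <- dq[a[e]] + flow[e]
      dq[b[e]] <- dq[b[e]] - flow[e]
    }
    q <- q + dq
  }
  q[seq_len(n)]
}

#' The 14-descriptor electronic/topological atom block
#'
#' A fixed, documented set of 14 per-atom descriptors of the two families
#' used by circular-fingerprint SOM baselines: (1) Gasteiger-type PEOE
#' partial charge, (2) Pauling electronegativity, (3) atomic polarizability,
#' (4) heavy-atom degree, (5) total valence (bond order sum + attached H),
#' (6) attached hydrogens, (7) formal charge, (8) aromatic indicator,
#' (9) ring indicator, (10) smallest containing ring size (0 if acyclic),
#' (11) topological distance to the nearest heteroatom, (12) topological
#' distance to the nearest ring atom, (13) number of heteroatom neighbours,
#' (14) node eccentricity within its fragment. Undefined distances use the
#' sentinel (molecule diameter + 1).
#'
#' @param graph An `atom_graph`.
#' @param atom_idx Optional 1-based atom index; default all atoms.
#' @return Numeric matrix `n x 14` (or a single row).
#' @export
atom_descriptors <- function(graph, atom_idx = NULL) {
  n <- graph$n
  D <- .topo_dist(graph)
  finite_max <- function(x) if (any(is.finite(x))) max(x[is.finite(x)]) else 0
  diam <- finite_max(D)
  sentinel <- diam + 1
  q <- .gasteiger_charges(graph)
  hetero <- !(graph$element %in% c("C", "H"))
  bond_sum <- numeric(n)
  if (nrow(graph$bonds)) {
    for (b in seq_len(nrow(graph$bonds))) {
      o <- graph$bonds$order[b]
      bond_sum[graph$bonds$i[b]] <- bond_sum[graph$bonds$i[b]] + o
      bond_sum[graph$bonds$j[b]] <- bond_sum[graph$bonds$j[b]] + o
    }
  }
  adj <- .adjacency(graph)
  d_het <- vapply(seq_len(n), function(k) {
    others <- which(hetero & seq_len(n) != k)
    if (!length(others)) return(sentinel)
    v <- D[k, others]; if (any(is.finite(v))) min(v) else sentinel
  }, numeric(1))
  d_ring <- vapply(seq_len(n), function(k) {
    others <- which(graph$ring)
    if (!length(others)) return(sentinel)
    v <- D[k, others]; if (any(is.finite(v))) min(v) else sentinel
  }, numeric(1))
  ecc <- vapply(seq_len(n), function(k) finite_max(D[k, ]), numeric(1))
  het_nb <- vapply(seq_len(n), function(k) sum(hetero[adj[[k]]]), numeric(1))
  M <- cbind(
    peoe_charge = q,
    electronegativity = unname(ifelse(is.na(.ELECTRONEG[graph$element]), 2.55,
                                      .ELECTRONEG[graph$element])),
    polarizability = unname(ifelse(is.na(.POLARIZ[graph$element]), 1.76,
                                   .POLARIZ[graph$element])),
    degree = graph$degree,
    valence = bond_sum + graph$n_h,
    n_h = graph$n_h,
    formal_charge = graph$charge,
    aromatic = as.numeric(graph$aromatic),
    ring = as.numeric(graph$ring),
    ring_size_min = graph$ring_size_min,
    dist_heteroatom = d_het,
    dist_ring = d_ring,
    hetero_neighbours = het_nb,
    eccentricity = ecc
  )
  if (!is.null(atom_idx)) {
    if (any(atom_idx < 1 | atom_idx > n)) stop("atom index out of range")
    M <- M[atom_idx, , drop = FALSE]
  }
  M
}

#' Atom-type key for uncertainty aggregation
#'
#' Halogens map to their bare element symbol; C, N, O and S map to
#' `"<El>-<HYB>"` (e.g. `"C-SP3"`); anything else falls back to
#' `"<El>-OTHER"`.
#'
#' @param graph An `atom_graph`.
#' @param atom_idx Optional indices; default all atoms.
#' @return Character vector of keys.
#' @export
atom_type_key <- function(graph, atom_idx = NULL) {
  if (is.null(atom_idx)) atom_idx <- seq_len(graph$n)
  if (any(atom_idx < 1 | atom_idx > graph$n)) stop("atom index out of range")
  el <- graph$element[atom_idx]
  hyb <- graph$hyb[atom_idx]
  ifelse(el %in% HALOGENS, el,
         ifelse(el %in% c("C", "N", "O", "S"), paste0(el, "-", hyb),
                paste0(el, "-OTHER")))
}
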