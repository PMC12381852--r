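#' @importFrom methods is as
#' @importFrom stats setNames
NULL

#' Halogen element symbols
#'
#' The four halogens (F, Cl, Br, I) used as the default target-element set
#' of the perturbation experiments.
#' @export
HALOGENS <- c("F", "Cl", "Br", "I")

# default valences used to infer implicit hydrogen counts from a kekulized
# connection table; charge shifts the effective valence (N+ -> 4, O- -> 1, ...)
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

# V2000 atom-block charge codes
.V2000_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                   `6` = -2, `7` = -3)

#' Create a molecule record
#'
#' A `molecule_record` holds one molecule (as SMILES), its heavy-atom count,
#' and a per-heavy-atom binary SOM annotation. Atom indices are 1-based and
#' refer to the heavy atoms in the order of the parsed structure; the same
#' convention is used in all files read and written by the package.
#'
#' @param id Molecule identifier (character scalar).
#' @param smiles Structure as a SMILES string (may contain multiple
#'   fragments, e.g. salts).
#' @param n_heavy Number of non-hydrogen atoms.
#' @param som_indices Integer vector of 1-based heavy-atom indices that are
#'   sites of metabolism. May be empty.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `molecule_record` with fields `id`, `smiles`,
#'   `n_heavy`, `som_indices`, `labels` (binary vector of length `n_heavy`)
#'   and `meta`.
#' @export
molecule_record <- function(id, smiles, n_heavy, som_indices = integer(0),
                            meta = list()) {
  som_indices <- sort(unique(as.integer(som_indices)))
  if (length(som_indices) &&
      (min(som_indices) < 1L || max(som_indices) > n_heavy)) {
    stop("som_indices out of range [1, n_heavy] for molecule '", id, "'")
  }
  labels <- integer(n_heavy)
  labels[som_indices] <- 1L
  structure(
    list(id = as.character(id), smiles = smiles, n_heavy = as.integer(n_heavy),
         som_indices = som_indices, labels = labels, meta = meta),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s: %s | %d heavy atoms, %d SOM>\n",
              x$id, x$smiles, x$n_heavy, length(x$som_indices)))
  invisible(x)
}

# Parse one ChemmineR SDF object into the internal connection table.
# Explicit hydrogens are folded into their heavy neighbour's H count and the
# heavy atoms renumbered in original order.
.parse_sdf <- function(sdf, id = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n_all <- length(elements)
  charge_code <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"]) else
    rep("0", n_all)
  charge <- unname(.V2000_CHARGE[charge_code])
  charge[is.na(charge)] <- 0
  if (is.null(dim(bb)) && length(bb)) bb <- matrix(bb, nrow = 1,
                                                   dimnames = list(NULL, names(bb)))
  if (is.null(bb) || nrow(bb) == 0 || !all(c("C1", "C2", "C3") %in% colnames(bb))) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(i = as.integer(bb[, "C1"]), j = as.integer(bb[, "C2"]),
                        order = as.integer(bb[, "C3"]))
  }
  heavy <- which(elements != "H")
  new_idx <- rep(NA_integer_, n_all)
  new_idx[heavy] <- seq_along(heavy)
  # count explicit hydrogens per heavy atom, then drop H rows/bonds
  expl_h <- integer(length(heavy))
  keep <- logical(nrow(bonds))
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      hi <- elements[i] == "H"; hj <- elements[j] == "H"
      if (hi && hj) next
      if (hi) expl_h[new_idx[j]] <- expl_h[new_idx[j]] + 1L
      else if (hj) expl_h[new_idx[i]] <- expl_h[new_idx[i]] + 1L
      else keep[b] <- TRUE
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  bonds$i <- new_idx[bonds$i]; bonds$j <- new_idx[bonds$j]
  list(id = id, element = elements[heavy], charge = charge[heavy],
       explicit_h = expl_h, bonds = bonds, orig_map = new_idx, sdf = sdf)
}

# parse SMILES into a plain list of ChemmineR SDF objects (one per parsed
# molecule, order preserved); ok flags which inputs parsed
.smiles_to_sdfset <- function(smiles, ids) {
  res <- suppressWarnings(try(ChemmineR::smiles2sdf(setNames(smiles, ids)),
                              silent = TRUE))
  if (!inherits(res, "try-error") && length(res) == length(smiles)) {
    return(list(sdfs = lapply(seq_along(smiles), function(k) res[[k]]),
                ok = rep(TRUE, length(smiles))))
  }
  # batch failed: fall back to per-molecule parsing to isolate bad entries
  ok <- logical(length(smiles))
  parts <- list()
  for (k in seq_along(smiles)) {
    r <- suppressWarnings(try(ChemmineR::smiles2sdf(setNames(smiles[k], ids[k])),
                              silent = TRUE))
    if (!inherits(r, "try-error")) {
      ok[k] <- TRUE
      parts[[length(parts) + 1L]] <- r[[1]]
    }
  }
  if (!length(parts)) return(list(sdfs = NULL, ok = ok))
  list(sdfs = parts, ok = ok)
}

.parse_som_field <- function(x, sep = "[;[:space:]]+") {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") return(integer(0))
  as.integer(strsplit(x, sep)[[1]])
}

#' Read molecules with SOM annotations
#'
#' Reads an SDF (V2000) file carrying 1-based SOM indices in a `SOM_LABELS`
#' molecule property (whitespace- or semicolon-separated), or a CSV table
#' with columns `id`, `smiles`, `som_indices` (semicolon-separated, 1-based,
#' empty allowed). Unparseable entries are skipped with a warning; the skip
#' count is attached as attribute `n_skipped`.
#'
#' @param path Path to the input file.
#' @param format Either `"sdf"` or `"smiles-table"`.
#' @return A list of [molecule_record()] objects, attribute `n_skipped`.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles-table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  n_skipped <- 0L
  if (format == "sdf") {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdfset)
    n_skipped <- sum(!valid)
    sdfset <- sdfset[valid]
    if (length(sdfset) == 0) stop("no parseable molecules in ", path)
    ids <- ChemmineR::sdfid(sdfset)
    ids[is.na(ids) | ids == ""] <- paste0("mol", which(is.na(ids) | ids == ""))
    records <- vector("list", length(sdfset))
    for (k in seq_along(sdfset)) {
      sdf <- sdfset[[k]]
      ct <- .parse_sdf(sdf, ids[k])
      db <- ChemmineR::datablock(sdf)
      som <- if ("SOM_LABELS" %in% names(db))
        .parse_som_field(db[["SOM_LABELS"]]) else integer(0)
      smi <- tryCatch(as.character(ChemmineR::sdf2smiles(sdf)),
                      error = function(e) NA_character_)
      records[[k]] <- molecule_record(ids[k], smi, length(ct$element), som)
      records[[k]]$conn <- ct
    }
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("id", "smiles", "som_indices")
    if (!all(need %in% names(tab))) {
      stop("smiles-table must have columns id, smiles, som_indices")
    }
    parsed <- .smiles_to_sdfset(tab$smiles, tab$id)
    n_skipped <- sum(!parsed$ok)
    if (is.null(parsed$sdfs)) stop("no parseable molecules in ", path)
    rows <- which(parsed$ok)
    records <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      ct <- .parse_sdf(parsed$sdfs[[k]], tab$id[r])
      som <- .parse_som_field(tab$som_indices[r])
      records[[k]] <- molecule_record(tab$id[r], tab$smiles[r],
                                      length(ct$element), som)
      records[[k]]$conn <- ct
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " unparseable entr",
            if (n_skipped == 1) "y" else "ies", " skipped in ", path)
  }
  attr(records, "n_skipped") <- n_skipped
  records
}

#' Write molecules with SOM annotations
#'
#' Inverse of [read_molecules()]: writes records either as an SDF with a
#' `SOM_LABELS` property or as a `id,smiles,som_indices` CSV.
#'
#' @param records List of [molecule_record()] objects.
#' @param path Output file path.
#' @param format Either `"sdf"` or `"smiles-table"`.
#' @return Invisibly, `path`.
#' @export
write_molecules <- function(records, path, format = c("sdf", "smiles-table")) {
  format <- match.arg(format)
  ids <- vapply(records, `[[`, character(1), "id")
  if (format == "smiles-table") {
    tab <- data.frame(
      id = ids,
      smiles = vapply(records, `[[`, character(1), "smiles"),
      som_indices = vapply(records, function(r)
        paste(r$som_indices, collapse = ";"), character(1)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    smiles <- vapply(records, `[[`, character(1), "smiles")
    sdfset <- suppressWarnings(try(
      ChemmineR::smiles2sdf(setNames(smiles, ids)), silent = TRUE))
    if (inherits(sdfset, "try-error")) {
      stop("cannot render structures to SDF for records in this set")
    }
    ChemmineR::datablock(sdfset) <- lapply(records, function(r)
      c(SOM_LABELS = paste(r$som_indices, collapse = " ")))
    ChemmineR::write.SDF(sdfset, path, cid = TRUE)
  }
  invisible(path)
}

.hyb_of <- function(element, aromatic, n_double, n_triple) {
  ifelse(aromatic, "SP2",
         ifelse(n_triple > 0 | n_double >= 2, "SP",
                ifelse(n_double >= 1, "SP2", "SP3")))
}

#' Build the heavy-atom graph of a molecule
#'
#' Parses the record's structure and assembles an undirected heavy-atom graph
#' with per-atom descriptors (element, hybridization, formal charge,
#' aromaticity, ring membership, heavy-atom degree, attached hydrogens,
#' smallest containing ring) and per-bond descriptors (order, aromatic,
#' conjugated, ring). Hydrogens are never nodes: explicit hydrogens are
#' folded into the attached-H count, and implicit hydrogens are inferred from
#' default valences on the kekulized connection table.
#'
#' Hybridization is assigned by a deterministic rule: aromatic atoms are SP2;
#' otherwise a triple bond or two double bonds give SP, one double bond SP2,
#' else SP3. A bond is flagged conjugated when it is aromatic or when both of
#' its atoms are unsaturated (SP/SP2).
#'
#' @param record A [molecule_record()].
#' @return An object of class `atom_graph`: a list with `n`, per-atom vectors
#'   `element`, `charge`, `aromatic`, `ring`, `hyb`, `degree`, `n_h`,
#'   `ring_size_min` (0 for acyclic atoms), and `bonds`, a data frame with
#'   columns `i`, `j`, `order`, `aromatic`, `conjugated`, `ring` (each
#'   undirected bond stored once).
#' @export
build_graph <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  ct <- record$conn
  if (is.null(ct)) {
    parsed <- .smiles_to_sdfset(record$smiles, record$id)
    if (!all(parsed$ok)) stop("structure error for molecule '", record$id,
                              "': SMILES does not parse")
    ct <- .parse_sdf(parsed$sdfs[[1]], record$id)
  }
  n <- length(ct$element)
  if (n != record$n_heavy) stop("structure error for molecule '", record$id,
                                "': heavy-atom count mismatch")
  bonds <- ct$bonds
  # ring perception on the hydrogen-stripped structure
  ring_atoms <- integer(0); arom_atoms <- integer(0)
  ring_bond_keys <- character(0); arom_bond_keys <- character(0)
  ring_size_min <- rep(0L, n)
  if (nrow(bonds)) {
    rn <- tryCatch(ChemmineR::rings(ct$sdf, upper = 14, type = "all",
                                    arom = TRUE),
                   error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    rings <- rn$RINGS
    if (length(rings)) {
      # ring atom labels refer to the original atom numbering (with explicit H)
      for (rk in seq_along(rings)) {
        idx_orig <- as.integer(sub("^.*_", "", rings[[rk]]))
        # map original indices to heavy renumbering
        idx <- idx_orig
        if (!is.null(ct$orig_map)) idx <- ct$orig_map[idx_orig]
        ring_atoms <- union(ring_atoms, idx)
        sz <- length(idx)
        upd <- ring_size_min[idx] == 0L | ring_size_min[idx] > sz
        ring_size_min[idx[upd]] <- sz
        pairs <- cbind(idx, c(idx[-1], idx[1]))
        keys <- paste(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2]))
        ring_bond_keys <- union(ring_bond_keys, keys)
        if (isTRUE(rn$AROMATIC[[rk]])) {
          arom_atoms <- union(arom_atoms, idx)
          arom_bond_keys <- union(arom_bond_keys, keys)
        }
      }
    }
  }
  aromatic <- seq_len(n) %in% arom_atoms
  in_ring <- seq_len(n) %in% ring_atoms
  degree <- integer(n); n_double <- integer(n); n_triple <- integer(n)
  bond_sum <- numeric(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]; o <- bonds$order[b]
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bond_sum[i] <- bond_sum[i] + o; bond_sum[j] <- bond_sum[j] + o
      if (o == 2) { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
      if (o == 3) { n_triple[i] <- n_triple[i] + 1L; n_triple[j] <- n_triple[j] + 1L }
    }
  }
  defval <- unname(.DEFAULT_VALENCE[ct$element])
  defval[is.na(defval)] <- 4
  effval <- ifelse(ct$element %in% c("N", "O", "S", "P"),
                   defval + ct$charge, defval - abs(ct$charge))
  # sulfur/phosphorus hypervalence: grow effective valence to the bond sum
  effval <- pmax(effval, bond_sum + ct$explicit_h)
  implicit_h <- pmax(0, round(effval - bond_sum - ct$explicit_h))
  n_h <- as.integer(ct$explicit_h + implicit_h)
  hyb <- .hyb_of(ct$element, aromatic, n_double, n_triple)
  if (nrow(bonds)) {
    keys <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    b_arom <- keys %in% arom_bond_keys
    b_ring <- keys %in% ring_bond_keys
    unsat <- hyb %in% c("SP", "SP2")
    b_conj <- b_arom | (unsat[bonds$i] & unsat[bonds$j])
    bonds <- data.frame(i = bonds$i, j = bonds$j, order = bonds$order,
                        aromatic = b_arom, conjugated = b_conj, ring = b_ring)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0),
                        aromatic = logical(0), conjugated = logical(0),
                        ring = logical(0))
  }
  structure(
    list(id = ct$id, n = n, element = ct$element, charge = ct$charge,
         aromatic = aromatic, ring = in_ring, hyb = hyb, degree = degree,
         n_h = n_h, ring_size_min = ring_size_min, bonds = bonds),
    class = "atom_graph"
  )
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("<atom_graph %s: %d atoms, %d bonds, %d aromatic atoms>\n",
              x$id, x$n, nrow(x$bonds), sum(x$aromatic)))
  invisible(x)
}

# adjacency list (neighbours per atom), used by featurizers and rules
.adjacency <- function(graph) {
  adj <- vector("list", graph$n)
  for (k in seq_len(graph$n)) adj[[k]] <- integer(0)
  if (nrow(graph$bonds)) {
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# all-pairs shortest path (BFS) on the heavy-atom graph; Inf across fragments
.topo_dist <- function(graph) {
  n <- graph$n
  adj <- .adjacency(graph)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Write per-atom predictions
#'
#' Writes one row per heavy atom: molecule id, 1-based atom index, element,
#' ensemble (BMA) probability, binary call, total/aleatoric/epistemic
#' uncertainty in bits, and the reliability category from
#' [interpret_uncertainty()]. Values round-trip at 6-decimal precision.
#'
#' @param prediction_table Data frame as produced by
#'   [predict.som_ensemble()] (`$table`).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(prediction_table, path,
                              format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("molecule_id", "atom", "element", "bma", "call",
            "u_tot", "u_ale", "u_epi", "category")
  if (nrow(prediction_table) == 0) {
    warning("empty prediction table; writing header only")
    tab <- prediction_table[, intersect(cols, names(prediction_table)),
                            drop = FALSE]
  } else {
    missing_cols <- setdiff(cols, names(prediction_table))
    if (length(missing_cols)) stop("prediction table lacks columns: ",
                                   paste(missing_cols, collapse = ", "))
    tab <- prediction_table[, cols]
    for (cc in c("bma", "u_tot", "u_ale", "u_epi")) {
      tab[[cc]] <- round(tab[[cc]], 6)
    }
  }
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back a prediction table written by [write_predictions()]
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return Data frame with the columns documented in [write_predictions()].
#' @export
read_predictions <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
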