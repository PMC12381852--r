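# Rule-labeled synthetic molecule libraries. The generator assembles
# drug-like molecules from a fragment grammar (SMILES concatenation at free
# valences) and labels atoms with deterministic structural rules, emulating
# the statistical regime of curated SOM data sets: roughly 1 SOM per 10
# heavy atoms, a few SOMs per molecule, an adjustable fraction of
# halogenated molecules, and halogens consistently labeled non-SOM.

# Internal fragments have a free valence on both their first and last
# written atom, so plain string concatenation yields a valid SMILES; ring
# closure digits are reused only after closure, which SMILES permits.
.FRAGMENTS_INTERNAL <- c(
  phenylene     = "c1ccccc1",
  pyridylene    = "c1ccncc1",
  thiophene     = "c1ccsc1",
  furan         = "c1ccoc1",
  naphthalene   = "c1ccc2ccccc2c1",
  cyclohexylene = "C1CCCCC1",
  piperidine    = "C1CCNCC1",
  tetrahydropyran = "C1CCOCC1",
  amide         = "C(=O)N",
  reverse_amide = "NC(=O)",
  ester         = "C(=O)O",
  ketone        = "C(=O)",
  sulfonyl      = "S(=O)(=O)",
  ether_me      = "CO",
  amine_me      = "CN",
  ethylene      = "CC",
  propylene     = "CCC",
  isopropylidene = "C(C)C",
  ethanolamine  = "CCN",
  urea          = "NC(=O)N"
)

# terminal fragments attach once, at their first written atom
.FRAGMENTS_TERMINAL <- c(
  methyl = "C", hydroxyl = "O", amino = "N", nitrile = "C#N",
  methoxy = "OC", carboxyl = "C(=O)O", acetyl = "C(C)=O"
)

.FRAGMENTS_HALOGEN <- c(fluoro = "F", chloro = "Cl", bromo = "Br",
                        iodo = "I", trifluoromethyl = "C(F)(F)F")

#' Synthetic-library configuration
#'
#' @param n_molecules Number of molecules to generate.
#' @param n_fragments Range (length-2 integer) of internal fragments per
#'   molecule (default 2--5).
#' @param halogen_fraction Fraction of molecules receiving a halogen
#'   substituent (default 0.3).
#' @param target_ratio Informational target SOM:non-SOM ratio (default
#'   1/10); the realised ratio is reported by [apply_label_rules()].
#' @param noise_rate Label-flip rate applied by convention via
#'   [flip_noise()] (default 0).
#' @param seed RNG seed; generation is a pure function of the config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_molecules = 1000L, n_fragments = c(2L, 5L),
                         halogen_fraction = 0.3, target_ratio = 0.1,
                         noise_rate = 0, seed = 0L) {
  stopifnot(n_molecules >= 1, length(n_fragments) == 2,
            n_fragments[1] >= 1, n_fragments[2] >= n_fragments[1],
            halogen_fraction >= 0, halogen_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_fragments = as.integer(n_fragments),
                 halogen_fraction = halogen_fraction,
                 target_ratio = target_ratio, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate an unlabeled synthetic molecule library
#'
#' Deterministic given `cfg$seed`. Every molecule is a valid structure of
#' 5--50 heavy atoms assembled from the fragment grammar; a
#' `cfg$halogen_fraction` share carries at least one halogen.
#'
#' @param cfg A [synth_config()].
#' @return List of unlabeled [molecule_record()] objects (`som_indices`
#'   empty).
#' @export
generate_library <- function(cfg = synth_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  smiles <- character(cfg$n_molecules)
  for (k in seq_len(cfg$n_molecules)) {
    repeat {
      nf <- sample(cfg$n_fragments[1]:cfg$n_fragments[2], 1)
      frags <- sample(.FRAGMENTS_INTERNAL, nf, replace = TRUE)
      smi <- paste(frags, collapse = "")
      if (stats::runif(1) < cfg$halogen_fraction) {
        smi <- paste0(smi, sample(.FRAGMENTS_HALOGEN, 1))
      } else if (stats::runif(1) < 0.5) {
        smi <- paste0(smi, sample(.FRAGMENTS_TERMINAL, 1))
      }
      # heavy-atom count from the SMILES (uppercase+lowercase organic subset)
      n_heavy <- nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", smi)))
      if (n_heavy >= 5 && n_heavy <= 50) break
    }
    smiles[k] <- smi
  }
  ids <- sprintf("syn%04d", seq_len(cfg$n_molecules))
  parsed <- .smiles_to_sdfset(smiles, ids)
  if (any(!parsed$ok)) {
    stop("generation error: grammar produced invalid structures: ",
         paste(smiles[!parsed$ok], collapse = ", "))
  }
  records <- vector("list", cfg$n_molecules)
  for (k in seq_len(cfg$n_molecules)) {
    ct <- .parse_sdf(parsed$sdfs[[k]], ids[k])
    records[[k]] <- molecule_record(ids[k], smiles[k], length(ct$element))
    records[[k]]$conn <- ct
  }
  records
}

#' Construct a label rule
#'
#' A rule carries a human-readable pattern description and an executable
#' predicate `function(graph)` returning a logical vector over heavy atoms;
#' matching atoms are labeled SOM with probability `prob`.
#'
#' @param name Rule name.
#' @param pattern Human-readable description of the matched substructure.
#' @param predicate Function of an `atom_graph` returning a logical vector
#'   of length `graph$n`.
#' @param prob SOM assignment probability for matching atoms in `[0, 1]`.
#' @return An object of class `label_rule`.
#' @export
label_rule <- function(name, pattern, predicate, prob = 1) {
  stopifnot(is.function(predicate), prob >= 0, prob <= 1)
  structure(list(name = name, pattern = pattern, predicate = predicate,
                 prob = prob), class = "label_rule")
}

# shared helper: sp3 carbons with >=1 H adjacent to atoms satisfying `sel`
.sp3_c_adjacent <- function(graph, sel) {
  adj <- .adjacency(graph)
  vapply(seq_len(graph$n), function(k) {
    graph$element[k] == "C" && graph$hyb[k] == "SP3" && graph$n_h[k] >= 1 &&
      any(sel[adj[[k]]])
  }, logical(1))
}

#' Default metabolic-lability label rules
#'
#' Deterministic structural heuristics used purely as label-generating
#' machinery (no mechanistic claim): benzylic/allylic carbons, carbons
#' alpha to nitrogen, and carbons alpha to oxygen, each restricted to
#' acyclic sp3 carbons carrying at least one hydrogen.
#'
#' @return List of [label_rule()] objects (first-match precedence).
#' @export
default_label_rules <- function() {
  list(
    label_rule("benzylic", "acyclic sp3 C-H adjacent to an aromatic atom",
               function(g) .sp3_c_adjacent(g, g$aromatic) & !g$ring),
    label_rule("alpha_to_N", "sp3 C-H adjacent to nitrogen",
               function(g) .sp3_c_adjacent(g, g$element == "N")),
    label_rule("alpha_to_O", "acyclic sp3 C-H adjacent to oxygen",
               function(g) .sp3_c_adjacent(g, g$element == "O") & !g$ring)
  )
}

#' Apply label rules to a molecule library
#'
#' Atoms matching a rule are labeled SOM with that rule's probability,
#' first-match precedence. Halogen atoms are forced to non-SOM by default,
#' mirroring the consistent non-SOM annotation of halogens in curated data.
#' The realised global SOM:non-SOM ratio is attached as attribute
#' `som_ratio`; zero realised positives is an error.
#'
#' @param molecules List of [molecule_record()] objects.
#' @param rules List of [label_rule()] objects (nonempty).
#' @param cfg A [synth_config()] (supplies the seed for probabilistic
#'   rules).
#' @param halogen_som If `FALSE` (default), halogens are never labeled SOM.
#' @return Labeled records; attributes `som_ratio` (positives/negatives)
#'   and `mean_soms_per_molecule`.
#' @export
apply_label_rules <- function(molecules, rules = default_label_rules(),
                              cfg = synth_config(), halogen_som = FALSE) {
  if (!length(rules)) stop("rules must be nonempty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 777L)
  total_pos <- 0L; total_atoms <- 0L
  out <- vector("list", length(molecules))
  for (k in seq_along(molecules)) {
    rec <- molecules[[k]]
    g <- build_graph(rec)
    assigned <- rep(FALSE, g$n)
    labels <- integer(g$n)
    for (rule in rules) {
      hits <- which(rule$predicate(g) & !assigned)
      if (length(hits)) {
        assigned[hits] <- TRUE
        draw <- stats::runif(length(hits)) < rule$prob
        labels[hits[draw]] <- 1L
      }
    }
    if (!halogen_som) labels[g$element %in% HALOGENS] <- 0L
    rec2 <- molecule_record(rec$id, rec$smiles, rec$n_heavy, which(labels == 1L),
                            meta = rec$meta)
    rec2$conn <- rec$conn
    out[[k]] <- rec2
    total_pos <- total_pos + sum(labels)
    total_atoms <- total_atoms + g$n
  }
  if (total_pos == 0L) stop("labeling error: no positive labels realised")
  attr(out, "som_ratio") <- total_pos / (total_atoms - total_pos)
  attr(out, "mean_soms_per_molecule") <- total_pos / length(molecules)
  out
}

#' Flip labels of predicate-matching atoms with probability eta
#'
#' Independent Bernoulli label noise restricted to a designated atom class.
#'
#' @param records Labeled records.
#' @param predicate Function of an `atom_graph` returning a logical vector
#'   (the targeted atoms).
#' @param eta Flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Records with flipped labels; attribute `n_flipped`.
#' @export
flip_noise <- function(records, predicate, eta, seed = 0L) {
  stopifnot(eta >= 0, eta <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_flipped <- 0L
  out <- lapply(records, function(rec) {
    g <- build_graph(rec)
    target <- which(predicate(g))
    if (!length(target)) return(rec)
    flip <- target[stats::runif(length(target)) < eta]
    if (!length(flip)) return(rec)
    labels <- rec$labels
    labels[flip] <- 1L - labels[flip]
    n_flipped <<- n_flipped + length(flip)
    rec2 <- molecule_record(rec$id, rec$smiles, rec$n_heavy,
                            which(labels == 1L), meta = rec$meta)
    rec2$conn <- rec$conn
    rec2
  })
  attr(out, "n_flipped") <- n_flipped
  out
}

.contains_element <- function(rec, elements) {
  g <- build_graph(rec)
  any(g$element %in% elements)
}

#' Drop molecules containing given elements
#'
#' @param records List of records.
#' @param elements Character vector of element symbols (nonempty).
#' @return The subset of records with no atom of the listed elements.
#' @export
exclude_element <- function(records, elements = HALOGENS) {
  stopifnot(length(elements) > 0)
  keep <- !vapply(records, .contains_element, logical(1), elements)
  out <- records[keep]
  if (!length(out)) warning("exclude_element removed every molecule")
  out
}

#' Duplicate element-containing molecules with mislabeled element atoms
#'
#' Every record containing a listed element is duplicated; in the duplicate
#' all atoms of those elements are labeled SOM (other labels unchanged).
#' Across the output the listed element atoms are split equally between the
#' two labels, emulating maximal label noise on that atom class.
#'
#' @param records List of records.
#' @param elements Element symbols (default halogens).
#' @return Augmented record list of length `N + n_containing`.
#' @export
inject_element_noise <- function(records, elements = HALOGENS) {
  has <- vapply(records, .contains_element, logical(1), elements)
  if (!any(has)) stop("contract error: no record contains ",
                      paste(elements, collapse = "/"))
  dups <- lapply(records[has], function(rec) {
    g <- build_graph(rec)
    labels <- rec$labels
    labels[g$element %in% elements] <- 1L
    rec2 <- molecule_record(paste0(rec$id, "_noisy"), rec$smiles, rec$n_heavy,
                            which(labels == 1L), meta = rec$meta)
    rec2$conn <- rec$conn
    rec2
  })
  c(records, dups)
}
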