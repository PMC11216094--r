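#' Atomic-descriptor configuration
#'
#' Node features are built from three descriptor blocks, concatenated in fixed
#' order, each of which can be switched off for ablation studies:
#'
#' * **species** - one-hot encoding of the element over the library vocabulary;
#' * **charge** - empirical Gasteiger partial charge (iterative
#'   electronegativity equalization, computed by Open Babel) plus formal
#'   charge;
#' * **neighbor_info** - heavy-atom degree, counts of neighboring atoms by
#'   element class (C, N, O, halogen, S), an aromaticity flag, and a
#'   ring-membership flag.
#'
#' The feature length is the sum of the enabled block widths and is identical
#' for every atom of every molecule in a run.
#'
#' @param use_species,use_charge,use_neighbor_info Block switches; at least
#'   one must be `TRUE`.
#' @param elements Element vocabulary for the one-hot block (and the neighbor
#'   element classes). The default covers every element occurring in the
#'   reagent library.
#' @param explicit_h Build all-atom graphs with explicit hydrogens instead of
#'   heavy-atom graphs.
#' @return A `descriptor_config` object; `feature_length` gives the total
#'   width.
#' @examples
#' descriptor_config(use_charge = FALSE)$feature_length
#' @export
descriptor_config <- function(use_species = TRUE, use_charge = TRUE,
                              use_neighbor_info = TRUE,
                              elements = c("C", "N", "O", "F", "S", "Cl", "Br", "I", "H"),
                              explicit_h = FALSE) {
  if (!any(use_species, use_charge, use_neighbor_info)) {
    stop("at least one descriptor block must be enabled", call. = FALSE)
  }
  widths <- c(species = if (use_species) length(elements) else 0L,
              charge = if (use_charge) 2L else 0L,
              neighbor_info = if (use_neighbor_info) 8L else 0L)
  structure(list(use_species = use_species, use_charge = use_charge,
                 use_neighbor_info = use_neighbor_info, elements = elements,
                 explicit_h = explicit_h, block_widths = widths,
                 feature_length = sum(widths)),
            class = "descriptor_config")
}

#' @export
print.descriptor_config <- function(x, ...) {
  on <- names(x$block_widths)[x$block_widths > 0]
  cat("<descriptor_config>", paste(on, collapse = " + "),
      sprintf("(%d features/atom)\n", x$feature_length))
  invisible(x)
}

# --- Open Babel conversion helpers -----------------------------------------

ob_options <- data.frame(names = "partialcharge", args = "gasteiger")

convert_smiles_batch <- function(smiles, to, extra_options = NULL) {
  ids <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = " ", collapse = "\n"), "\n")
  opts <- rbind(ob_options, extra_options)
  ChemmineOB::convertFormat("SMI", to, src, options = opts)
}

# Minimal TRIPOS MOL2 reader (no installed R package reads MOL2). Returns one
# record per molecule: title, elements, gasteiger charges, aromatic flags, and
# the bond list.
parse_mol2_batch <- function(text) {
  blocks <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    title <- trimws(lines[2])
    counts <- scan(text = lines[3], what = integer(), quiet = TRUE)
    n_atoms <- counts[1]
    n_bonds <- counts[2]
    ai <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
    atom_lines <- lines[(ai + 1):(ai + n_atoms)]
    af <- strsplit(trimws(atom_lines), "[[:space:]]+")
    types <- vapply(af, `[`, character(1), 6L)
    charges <- as.numeric(vapply(af, `[`, character(1), 9L))
    elements <- sub("\\..*$", "", types)
    elements <- paste0(toupper(substr(elements, 1, 1)),
                       tolower(substring(elements, 2)))
    aromatic <- grepl("\\.ar$", types)
    bonds <- matrix(integer(0), ncol = 3)
    if (n_bonds > 0) {
      bi <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)[1]
      bf <- strsplit(trimws(lines[(bi + 1):(bi + n_bonds)]), "[[:space:]]+")
      a1 <- as.integer(vapply(bf, `[`, character(1), 2L))
      a2 <- as.integer(vapply(bf, `[`, character(1), 3L))
      btype <- vapply(bf, `[`, character(1), 4L)
      bonds <- cbind(a1, a2, ar = as.integer(btype == "ar"))
      aromatic[c(a1[btype == "ar"], a2[btype == "ar"])] <- TRUE
    }
    list(title = title, elements = elements, charges = charges,
         aromatic = aromatic, bonds = bonds)
  })
}

# Formal charges from the "M  CHG" lines of an SDF written from the same
# SMILES batch (atom order is preserved by the converter).
sdf_formal_charges <- function(text) {
  blocks <- strsplit(text, "\\${4}")[[1]]
  blocks <- blocks[grepl("V2000", blocks)]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    cl <- grep("V2000", lines, fixed = TRUE)[1]
    n_atoms <- as.integer(substr(lines[cl], 1, 3))
    chg <- numeric(n_atoms)
    for (ln in grep("^M  CHG", lines, value = TRUE)) {
      f <- scan(text = sub("^M  CHG", "", ln), what = integer(), quiet = TRUE)
      n <- f[1]
      idx <- f[seq(2, by = 2, length.out = n)]
      val <- f[seq(3, by = 2, length.out = n)]
      chg[idx] <- val
    }
    chg
  })
}

# --- Featurization ----------------------------------------------------------

featurize_molecule <- function(mol, formal_charge, config) {
  n <- length(mol$elements)
  deg <- integer(n)
  in_ring <- logical(n)
  nb_elem <- matrix(0L, n, 5, dimnames = list(NULL, c("C", "N", "O", "hal", "S")))
  if (nrow(mol$bonds) > 0) {
    a1 <- mol$bonds[, 1]; a2 <- mol$bonds[, 2]
    deg <- tabulate(c(a1, a2), nbins = n)
    cls <- function(e) ifelse(e %in% c("F", "Cl", "Br", "I"), "hal", e)
    for (k in seq_along(a1)) {
      c2 <- cls(mol$elements[a2[k]]); c1 <- cls(mol$elements[a1[k]])
      if (c2 %in% colnames(nb_elem)) nb_elem[a1[k], c2] <- nb_elem[a1[k], c2] + 1L
      if (c1 %in% colnames(nb_elem)) nb_elem[a2[k], c1] <- nb_elem[a2[k], c1] + 1L
    }
    g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bridge_ids <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(bridge_ids))
    if (length(ring_edges)) {
      ends <- igraph::ends(g, ring_edges)
      in_ring[unique(as.integer(ends))] <- TRUE
    }
  }
  blocks <- list()
  if (config$use_species) {
    unknown <- setdiff(unique(mol$elements), config$elements)
    if (length(unknown)) {
      stop("element(s) outside the descriptor vocabulary in ", mol$title,
           ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    onehot <- matrix(0, n, length(config$elements),
                     dimnames = list(NULL, paste0("species_", config$elements)))
    onehot[cbind(seq_len(n), match(mol$elements, config$elements))] <- 1
    blocks$species <- onehot
  }
  if (config$use_charge) {
    if (anyNA(mol$charges) || any(!is.finite(mol$charges))) {
      stop("partial-charge computation failed for atom(s) ",
           paste(which(!is.finite(mol$charges)), collapse = ", "),
           " of ", mol$title, call. = FALSE)
    }
    blocks$charge <- cbind(charge_gasteiger = mol$charges,
                           charge_formal = formal_charge)
  }
  if (config$use_neighbor_info) {
    blocks$neighbor_info <- cbind(nb_degree = deg,
                                  nb_C = nb_elem[, "C"], nb_N = nb_elem[, "N"],
                                  nb_O = nb_elem[, "O"], nb_halogen = nb_elem[, "hal"],
                                  nb_S = nb_elem[, "S"],
                                  nb_aromatic = as.numeric(mol$aromatic),
                                  nb_ring = as.numeric(in_ring))
  }
  do.call(cbind, blocks)
}

#' Convert SMILES to attributed molecular graphs
#'
#' Parses each SMILES with Open Babel, computes Gasteiger partial charges,
#' perceives aromaticity, and assembles an undirected molecular graph whose
#' nodes carry the descriptor vectors of [descriptor_config()]. Graphs are
#' heavy-atom graphs unless `config$explicit_h` is set.
#'
#' @param smiles Character vector of SMILES.
#' @param config A [descriptor_config()].
#' @param keys Optional identifiers attached to the graphs (defaults to the
#'   SMILES strings).
#' @return For `mol_graphs()`, a list of `mol_graph` objects; each has `n`
#'   (node count), `elements`, `features` (`n x feature_length` matrix),
#'   `edges` (two-column matrix of symmetric directed pairs, no self-loops),
#'   `smiles`, and `key`. `mol_to_graph()` is the single-molecule wrapper.
#' @examples
#' g <- mol_to_graph("CC", descriptor_config())
#' g$n       # 2 heavy atoms
#' nrow(g$edges)  # 2 directed edges for the single bond
#' @export
mol_graphs <- function(smiles, config = descriptor_config(), keys = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            inherits(config, "descriptor_config"))
  if (is.null(keys)) keys <- smiles
  stopifnot(length(keys) == length(smiles))
  extra <- if (config$explicit_h) data.frame(names = "h", args = "") else NULL
  mol2 <- parse_mol2_batch(convert_smiles_batch(smiles, "MOL2", extra))
  sdf <- sdf_formal_charges(convert_smiles_batch(smiles, "SDF", extra))
  if (length(mol2) != length(smiles) || length(sdf) != length(smiles)) {
    got <- vapply(mol2, `[[`, character(1), "title")
    bad <- setdiff(paste0("m", seq_along(smiles)), got)
    stop("SMILES failed to parse: ",
         paste(utils::head(smiles[as.integer(sub("m", "", bad))], 5),
               collapse = "; "), call. = FALSE)
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    mol <- mol2[[i]]
    mol$title <- keys[i]
    if (length(sdf[[i]]) != length(mol$elements)) {
      stop("atom count mismatch between converters for ", keys[i], call. = FALSE)
    }
    feats <- featurize_molecule(mol, sdf[[i]], config)
    edges <- if (nrow(mol$bonds) > 0) {
      rbind(mol$bonds[, 1:2, drop = FALSE],
            mol$bonds[, 2:1, drop = FALSE])
    } else {
      matrix(integer(0), ncol = 2)
    }
    colnames(edges) <- c("src", "dst")
    out[[i]] <- structure(list(smiles = smiles[i], key = keys[i],
                               n = length(mol$elements),
                               elements = mol$elements,
                               features = feats, edges = edges,
                               config = config),
                          class = "mol_graph")
  }
  out
}

#' @rdname mol_graphs
#' @export
mol_to_graph <- function(smiles, config = descriptor_config(), keys = NULL) {
  stopifnot(length(smiles) == 1)
  mol_graphs(smiles, config, keys)[[1]]
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d features/atom\n",
              x$key, x$n, nrow(x$edges) / 2, ncol(x$features)))
  invisible(x)
}

#' Is a molecular graph connected?
#'
#' @param graph A `mol_graph`.
#' @return TRUE if every atom is reachable from every other.
#' @export
graph_is_connected <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  if (graph$n <= 1) return(TRUE)
  if (nrow(graph$edges) == 0) return(FALSE)
  g <- igraph::graph_from_edgelist(unique(t(apply(graph$edges, 1, sort))),
                                   directed = FALSE)
  if (igraph::vcount(g) < graph$n) return(FALSE)
  igraph::is_connected(g)
}
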