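#' Structure registry for cyclic hypervalent halogen reagents
#'
#' The chemical space of the study is spanned by cyclic skeletons holding a
#' hypervalent halogen(III) center, a halogen identity (I, Br, Cl), and a
#' transfer group bound to the center. Skeleton templates are SMILES strings
#' with two placeholders: `{X}` for the halogen center and `{G}` for the
#' transfer-group attachment. Both tables are stored as version-controlled TSV
#' files under `inst/extdata/` so the space can be extended without code
#' changes.
#'
#' Skeletons 1-5 are the combinatorial library (benziodoxolone, gem-dimethyl
#' and gem-bis(trifluoromethyl) benziodoxoles, benziodazolone, and the
#' biphenylene-bridged dibenzohalole); skeleton 6 (sulfonate-bridged
#' benziodoxathiole dioxide) is used only for external validation. The
#' hypervalent center is written as a plain trivalent neutral halogen; Open
#' Babel parses this 10-X-3 convention without charge separation, and the same
#' convention is applied uniformly across the registry.
#'
#' @param skeletons_path,groups_path Optional paths overriding the packaged
#'   registry TSV files.
#' @return A list of class `reagent_registry` with data frames `skeletons`
#'   (`skeleton_id`, `template_smiles`, `description`) and `groups`
#'   (`group_id`, `group_smiles`, `label`).
#' @examples
#' reg <- reagent_registry()
#' reg$skeletons$skeleton_id
#' @export
reagent_registry <- function(skeletons_path = NULL, groups_path = NULL) {
  if (is.null(skeletons_path)) skeletons_path <- extdata_file("skeletons.tsv")
  if (is.null(groups_path)) groups_path <- extdata_file("transfer_groups.tsv")
  sk <- read.delim(skeletons_path, stringsAsFactors = FALSE, colClasses = "character")
  gr <- read.delim(groups_path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("skeleton_id", "template_smiles") %in% names(sk)),
            all(c("group_id", "group_smiles", "label") %in% names(gr)))
  if (anyDuplicated(sk$skeleton_id)) stop("duplicate skeleton_id in registry")
  if (anyDuplicated(gr$group_id)) stop("duplicate group_id in registry")
  bad <- !grepl("\\{X\\}", sk$template_smiles) | !grepl("\\{G\\}", sk$template_smiles)
  if (any(bad)) {
    stop("skeleton template(s) missing {X}/{G} placeholders: ",
         paste(sk$skeleton_id[bad], collapse = ", "))
  }
  structure(list(skeletons = sk, groups = gr), class = "reagent_registry")
}

#' @export
print.reagent_registry <- function(x, ...) {
  cat("<reagent_registry>", nrow(x$skeletons), "skeletons,",
      nrow(x$groups), "transfer groups\n")
  invisible(x)
}

HALOGENS <- c("I", "Br", "Cl")

registry_lookup <- function(table, key_col, ids, what) {
  idx <- match(as.character(ids), table[[key_col]])
  if (anyNA(idx)) {
    stop("unknown ", what, " id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  table[idx, , drop = FALSE]
}

#' Canonicalize SMILES strings
#'
#' Round-trips SMILES through Open Babel's canonical writer. Strings that do
#' not parse raise an error naming the offending input.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("m", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = " ", collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  got <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
  res <- can[match(ids, got)]
  bad <- is.na(res) | !nzchar(res)
  if (any(bad)) {
    stop("SMILES failed to parse/canonicalize: ",
         paste(utils::head(smiles[bad], 5), collapse = "; "), call. = FALSE)
  }
  unname(res)
}

#' Assemble the SMILES of one reagent
#'
#' Substitutes the halogen symbol and the transfer-group fragment into a
#' skeleton template and validates the result by parsing and canonicalizing it.
#' Assembly is deterministic: a fixed (skeleton, halogen, group) always yields
#' a byte-identical canonical SMILES.
#'
#' @param skeleton_id Skeleton identifier present in the registry.
#' @param halogen One of `"I"`, `"Br"`, `"Cl"`.
#' @param group_id Transfer-group identifier present in the registry.
#' @param registry A [reagent_registry()].
#' @param canonical Return the canonical form (default) or the raw substituted
#'   string.
#' @return A single SMILES string.
#' @examples
#' assemble_smiles(1, "I", "a")
#' @export
assemble_smiles <- function(skeleton_id, halogen, group_id,
                            registry = reagent_registry(), canonical = TRUE) {
  halogen <- match.arg(halogen, HALOGENS)
  sk <- registry_lookup(registry$skeletons, "skeleton_id", skeleton_id, "skeleton")
  gr <- registry_lookup(registry$groups, "group_id", group_id, "transfer group")
  raw <- sub("{X}", halogen, sk$template_smiles, fixed = TRUE)
  raw <- sub("{G}", gr$group_smiles, raw, fixed = TRUE)
  if (!canonical) return(raw)
  can <- tryCatch(canonical_smiles(raw), error = function(e) {
    stop("assembly of (", skeleton_id, ", ", halogen, ", ", group_id,
         ") produced an unparsable structure: ", raw, call. = FALSE)
  })
  can
}

#' Enumerate the combinatorial reagent library
#'
#' Full Cartesian product of skeletons, halogen centers, and transfer groups,
#' in deterministic (skeleton, halogen, group) order, each combination carrying
#' its assembled canonical SMILES.
#'
#' @param skeleton_ids,halogens,group_ids Identifier vectors; every id must
#'   exist in the registry.
#' @param registry A [reagent_registry()].
#' @return A data frame with one row per reagent: `skeleton_id`, `halogen`,
#'   `group_id`, `group_label`, `key` (`"skeleton-halogen-group"`), `smiles`.
#' @examples
#' lib <- enumerate_reagents(1:2, "I", c("a", "h"))
#' nrow(lib)  # 4
#' @export
enumerate_reagents <- function(skeleton_ids = 1:5, halogens = HALOGENS,
                               group_ids = letters[1:20],
                               registry = reagent_registry()) {
  halogens <- vapply(halogens, match.arg, character(1), choices = HALOGENS)
  sk <- registry_lookup(registry$skeletons, "skeleton_id", skeleton_ids, "skeleton")
  gr <- registry_lookup(registry$groups, "group_id", group_ids, "transfer group")
  if (nrow(sk) == 0 || length(halogens) == 0 || nrow(gr) == 0) {
    return(data.frame(skeleton_id = character(0), halogen = character(0),
                      group_id = character(0), group_label = character(0),
                      key = character(0), smiles = character(0),
                      stringsAsFactors = FALSE))
  }
  combos <- expand.grid(group_i = seq_len(nrow(gr)), halogen = halogens,
                        skeleton_i = seq_len(nrow(sk)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder columns so the result
  # is sorted by (skeleton, halogen, group)
  out <- data.frame(
    skeleton_id = sk$skeleton_id[combos$skeleton_i],
    halogen = combos$halogen,
    group_id = gr$group_id[combos$group_i],
    group_label = gr$label[combos$group_i],
    stringsAsFactors = FALSE
  )
  out$key <- paste(out$skeleton_id, out$halogen, out$group_id, sep = "-")
  stopifnot(!anyDuplicated(out$key))
  raw <- mapply(function(tpl, x, g) sub("{G}", g, sub("{X}", x, tpl, fixed = TRUE), fixed = TRUE),
                sk$template_smiles[match(out$skeleton_id, sk$skeleton_id)],
                out$halogen,
                gr$group_smiles[match(out$group_id, gr$group_id)],
                USE.NAMES = FALSE)
  out$smiles <- canonical_smiles(raw)
  rownames(out) <- NULL
  out
}
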