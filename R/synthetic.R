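#' Specification for a synthetic BDE table
#'
#' Defines the statistical structure of a generated table: iodine-column BDEs
#' drawn from a normal distribution, bromine and chlorine columns linear in
#' the iodine column with homoscedastic Gaussian residuals, and optional
#' uniformly random missingness. Defaults emulate the homolytic study
#' conditions: the observed iodine distribution (mean 55.3, sd 12.4 kcal/mol)
#' and the fitted cross-halogen dependences (Br: 0.89 x - 13.85,
#' Cl: 0.76 x - 26.02).
#'
#' @param n_skeletons,n_groups Grid dimensions; `n_skeletons * n_groups >= 3`.
#' @param slope_br,intercept_br,slope_cl,intercept_cl True cross-halogen maps.
#' @param iodine_mean,iodine_sd Normal distribution of the iodine column,
#'   kcal/mol.
#' @param noise_sd Residual standard deviation, kcal/mol (>= 0).
#' @param missing_fraction Probability a cell is masked, in `[0, 1)`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_skeletons = 5, n_groups = 20,
                           slope_br = 0.89, intercept_br = -13.85,
                           slope_cl = 0.76, intercept_cl = -26.02,
                           iodine_mean = 55.3, iodine_sd = 12.4,
                           noise_sd = 3, missing_fraction = 0, seed = 1) {
  stopifnot(noise_sd >= 0, missing_fraction >= 0, missing_fraction < 1,
            n_skeletons * n_groups >= 3, iodine_sd > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic BDE table
#'
#' Emits records in the exact fixture schema used by [load_bde_table()], so
#' every downstream stage (scaling, splitting, cross-halogen fitting) is
#' format-agnostic about real versus synthetic data.
#'
#' @param spec A [synthetic_spec()].
#' @return A record data frame matching [bde_table()] output (with
#'   `bde_type = "synthetic"`), plus attribute `"spec"`.
#' @examples
#' tab <- generate_bde_table(synthetic_spec(noise_sd = 0, seed = 7))
#' fit_cross_halogen(tab, "Br")  # recovers slope 0.89 exactly
#' @export
generate_bde_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_cell <- spec$n_skeletons * spec$n_groups
  grid <- expand.grid(group_id = sprintf("g%02d", seq_len(spec$n_groups)),
                      skeleton_id = as.character(seq_len(spec$n_skeletons)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(spec$seed, {
    x <- rnorm(n_cell, spec$iodine_mean, spec$iodine_sd)
    br <- spec$slope_br * x + spec$intercept_br + rnorm(n_cell, 0, spec$noise_sd)
    cl <- spec$slope_cl * x + spec$intercept_cl + rnorm(n_cell, 0, spec$noise_sd)
    out <- data.frame(
      skeleton_id = rep(grid$skeleton_id, times = 3),
      halogen = rep(c("I", "Br", "Cl"), each = n_cell),
      group_id = rep(grid$group_id, times = 3),
      group_label = rep(grid$group_id, times = 3),
      bde_kcal_mol = c(x, br, cl),
      stringsAsFactors = FALSE
    )
    if (spec$missing_fraction > 0) {
      mask <- runif(nrow(out)) < spec$missing_fraction
      out$bde_kcal_mol[mask] <- NA_real_
    }
    out$key <- paste(out$skeleton_id, out$halogen, out$group_id, sep = "-")
    out$missing <- is.na(out$bde_kcal_mol)
    out$sentinel <- ifelse(out$missing, "-", "")
    out$bde_type <- "synthetic"
    attr(out, "spec") <- spec
    out
  })
}

#' Generate a toy molecular library with an exact composition rule
#'
#' Builds parseable SMILES of small acyclic organics (carbon/oxygen/nitrogen
#' chains with random halogen substituents on carbons) whose pseudo-BDE
#' targets are computed exactly by a documented closed-form rule on the atom
#' composition. Because the targets carry no noise and depend only on
#' composition, the library serves as a capacity control for the graph
#' network (a model with an extensive readout can fit it essentially
#' perfectly) and as a contrast case for descriptor ablations (species
#' information alone suffices).
#'
#' @param n_molecules Number of molecules.
#' @param rule Function mapping a named count vector (`C`, `N`, `O`, `F`,
#'   `Cl`, `Br`, `I`) to a numeric target. The default is
#'   `10 C + 5 O + 3 N + 8 F + 4 Cl + 2 Br + 1 I`.
#' @param seed Integer seed; the library is deterministic given it.
#' @return Data frame with `smiles`, `target`, and the composition counts.
#' @examples
#' toy <- generate_toy_library(5, seed = 1)
#' toy$target
#' @export
generate_toy_library <- function(n_molecules, rule = toy_composition_rule,
                                 seed = 1) {
  stopifnot(n_molecules >= 1, is.function(rule))
  halogens <- c("F", "Cl", "Br", "I")
  with_seed(seed, {
    rows <- lapply(seq_len(n_molecules), function(i) {
      len <- sample(3:8, 1)
      # heteroatoms sparse so chains stay chemically tame and parseable
      atoms <- sample(c("C", "C", "C", "C", "O", "N"), len, replace = TRUE)
      n_hal <- sample(0:2, 1)
      carbons <- which(atoms == "C")
      hal_at <- if (n_hal > 0 && length(carbons) > 0) {
        sample(carbons, min(n_hal, length(carbons)))
      } else {
        integer(0)
      }
      hal_sym <- if (length(hal_at)) sample(halogens, length(hal_at), replace = TRUE) else character(0)
      parts <- atoms
      for (j in seq_along(hal_at)) {
        parts[hal_at[j]] <- paste0(parts[hal_at[j]], "(", hal_sym[j], ")")
      }
      counts <- c(C = sum(atoms == "C"), N = sum(atoms == "N"),
                  O = sum(atoms == "O"),
                  F = sum(hal_sym == "F"), Cl = sum(hal_sym == "Cl"),
                  Br = sum(hal_sym == "Br"), I = sum(hal_sym == "I"))
      c(list(smiles = paste(parts, collapse = ""),
             target = unname(rule(counts))), as.list(counts))
    })
    out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  })
}

#' @rdname generate_toy_library
#' @param counts Named composition vector.
#' @export
toy_composition_rule <- function(counts) {
  10 * counts[["C"]] + 5 * counts[["O"]] + 3 * counts[["N"]] +
    8 * counts[["F"]] + 4 * counts[["Cl"]] + 2 * counts[["Br"]] + 1 * counts[["I"]]
}
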