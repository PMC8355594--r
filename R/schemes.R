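#' Ordered developmental population schemes
#'
#' A population scheme names the ordered thymocyte stages of one system,
#' the subset forming the double-negative (DN) compartment, and the
#' proportions used to composite those stages into a single "DN" profile.
#' The DN subsets are DN1-3 in mouse and Thy1-3 in human; compositing
#' weights reflect the measured proportion of each subset in the sorted DN
#' pool of that system.
#'
#' @param system Label for the system (e.g. `"M-THY"`).
#' @param stages Ordered character vector of stage names.
#' @param dn_members Prefix of `stages` composited as "DN".
#' @param dn_weights Named numeric vector over `dn_members`, summing to 1.
#' @return A `population_scheme` list.
#' @export
population_scheme <- function(system, stages, dn_members, dn_weights) {
  if (anyDuplicated(stages)) stop("Stage names must be unique.", call. = FALSE)
  if (!identical(dn_members, stages[seq_along(dn_members)])) {
    stop("`dn_members` must be a prefix of the stage ordering.", call. = FALSE)
  }
  if (!setequal(names(dn_weights), dn_members)) {
    stop("`dn_weights` must be named by exactly the DN members.", call. = FALSE)
  }
  dn_weights <- dn_weights[dn_members]
  if (abs(sum(dn_weights) - 1) > 1e-9) {
    stop("DN weights must sum to 1 (got ", sum(dn_weights), ").",
         call. = FALSE)
  }
  structure(
    list(system = system, stages = stages, dn_members = dn_members,
         dn_weights = dn_weights),
    class = "population_scheme"
  )
}

#' @rdname population_scheme
#' @export
scheme_mouse_thymus <- function() {
  population_scheme(
    system = "M-THY",
    stages = c("DN1", "DN2", "DN3", "ISP8", "DP early", "DP late",
               "SP8", "SP4"),
    dn_members = c("DN1", "DN2", "DN3"),
    dn_weights = c(DN1 = 0.04, DN2 = 0.03, DN3 = 0.93)
  )
}

#' @rdname population_scheme
#' @export
scheme_mouse_ato <- function() {
  population_scheme(
    system = "M-ATO",
    stages = c("DN1", "DN2", "DN3", "ISP8", "DP early", "DP late",
               "SP8", "SP4"),
    dn_members = c("DN1", "DN2", "DN3"),
    dn_weights = c(DN1 = 0.01, DN2 = 0.01, DN3 = 0.98)
  )
}

#' @rdname population_scheme
#' @export
scheme_human_thymus <- function() {
  population_scheme(
    system = "H-THY",
    stages = c("Thy1", "Thy2", "Thy3", "ISP4", "DP early", "DP late",
               "SP8", "SP4"),
    dn_members = c("Thy1", "Thy2", "Thy3"),
    dn_weights = c(Thy1 = 0.001, Thy2 = 0.599, Thy3 = 0.40)
  )
}

#' @rdname population_scheme
#' @export
scheme_human_ato <- function() {
  population_scheme(
    system = "H-ATO",
    stages = c("Thy1", "Thy2", "Thy3", "ISP4", "DP early", "DP late",
               "SP8"),
    dn_members = c("Thy1", "Thy2", "Thy3"),
    dn_weights = c(Thy1 = 0.001, Thy2 = 0.799, Thy3 = 0.20)
  )
}

#' Read a population scheme from YAML
#'
#' Expects keys `system`, `stages` (ordered list), `dn_members`,
#' `dn_weights` (mapping stage to proportion).
#'
#' @param path Path to a YAML file.
#' @return A [population_scheme()].
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  population_scheme(
    system = cfg$system,
    stages = unlist(cfg$stages),
    dn_members = unlist(cfg$dn_members),
    dn_weights = unlist(cfg$dn_weights)
  )
}

#' Gene panels: pathway to gene-list mapping
#'
#' @param panels Named list mapping pathway name to a nonempty character
#'   vector of gene identifiers. A gene may appear in several pathways.
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(panels) {
  if (length(panels) == 0 || is.null(names(panels)) ||
      any(names(panels) == "")) {
    stop("`panels` must be a named list of gene vectors.", call. = FALSE)
  }
  empty <- names(panels)[vapply(panels, length, 1L) == 0]
  if (length(empty) > 0) {
    stop("Empty gene list for pathway(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  panels <- lapply(panels, as.character)
  structure(panels, class = "gene_panel")
}

#' Read a gene panel from YAML
#'
#' Expects a mapping of pathway name to gene list.
#'
#' @param path Path to a YAML file.
#' @return A [gene_panel()].
#' @export
read_panel <- function(path) {
  gene_panel(yaml::read_yaml(path))
}
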