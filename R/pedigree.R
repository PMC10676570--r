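PED_ROLES <- c("paternal_grandfather", "paternal_grandmother",
               "maternal_grandfather", "maternal_grandmother",
               "father", "mother", "offspring")

#' Define a three-generation pedigree
#'
#' Binds the seven pedigree roles to individual IDs (columns of the
#' genotype table). The fixed role order — grandparents before parents,
#' males before females, offspring last — is the digit order of the
#' 7-digit genotype strings.
#'
#' @param paternal_grandfather,paternal_grandmother,maternal_grandfather,maternal_grandmother,father,mother
#'   individual IDs
#' @param offspring one or more offspring IDs (each is analysed
#'   separately against the same parents and grandparents)
#' @return a `pedigree_spec` list
#' @export
pedigree_spec <- function(paternal_grandfather, paternal_grandmother,
                          maternal_grandfather, maternal_grandmother,
                          father, mother, offspring) {
  ped <- list(paternal_grandfather = as.character(paternal_grandfather),
              paternal_grandmother = as.character(paternal_grandmother),
              maternal_grandfather = as.character(maternal_grandfather),
              maternal_grandmother = as.character(maternal_grandmother),
              father = as.character(father),
              mother = as.character(mother),
              offspring = as.character(offspring))
  lens <- lengths(ped)
  if (any(lens[PED_ROLES != "offspring"] != 1L) || lens[["offspring"]] < 1L) {
    stop("each role must bind exactly one ID (offspring: at least one)")
  }
  ids <- unlist(ped, use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("pedigree IDs must be distinct; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(ped, class = "pedigree_spec")
}

#' Read a pedigree specification from YAML
#'
#' The file maps the seven role keys (`paternal_grandfather`,
#' `paternal_grandmother`, `maternal_grandfather`, `maternal_grandmother`,
#' `father`, `mother`, `offspring`) to individual IDs; `offspring` may be
#' a list.
#'
#' @param path YAML file path
#' @return a `pedigree_spec`
#' @export
read_pedigree_spec <- function(path) {
  y <- yaml::read_yaml(path)
  missing_roles <- setdiff(PED_ROLES, names(y))
  if (length(missing_roles)) {
    stop("pedigree spec lacks role(s): ", paste(missing_roles, collapse = ", "))
  }
  do.call(pedigree_spec, y[PED_ROLES])
}

# role -> ID vector for one offspring, in genotype-string digit order
ped_ids <- function(ped, offspring) {
  c(ped$paternal_grandfather, ped$paternal_grandmother,
    ped$maternal_grandfather, ped$maternal_grandmother,
    ped$father, ped$mother, offspring)
}

check_ped_in_gt <- function(ped, gt) {
  ids <- unlist(ped, use.names = FALSE)
  absent <- setdiff(ids, gt_individuals(gt))
  if (length(absent)) {
    stop("pedigree ID(s) absent from genotype table: ",
         paste(absent, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.pedigree_spec <- function(x, ...) {
  cat("Three-generation pedigree:\n")
  for (r in PED_ROLES) {
    cat(sprintf("  %-21s %s\n", r, paste(x[[r]], collapse = ", ")))
  }
  invisible(x)
}
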