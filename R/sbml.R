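# SBML input/output for genome-scale metabolic models.
#
# Reads SBML Level 3 core with the fbc (flux bounds, gene products) and
# groups (subsystems) extension packages, plus the legacy notes dialect
# (GENE_ASSOCIATION / SUBSYSTEM paragraphs inside reaction notes). Writing
# emits Level 3 + fbc v2 + groups v1 with deterministic byte output.

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}

local_attr <- function(node, local_name) {
  at <- xml2::xml_attrs(node)
  hit <- grepl(paste0("(^|:)", local_name, "$"), names(at))
  if (!any(hit)) return(NA_character_)
  unname(at[which(hit)[1]])
}

notes_field <- function(node, key) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(NA_character_)
  txt <- xml2::xml_text(xml2::xml_find_all(notes, ".//*"))
  hit <- grep(paste0("^\\s*", key, "\\s*:"), txt, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[1]))
}

# Convert an fbc geneProductAssociation subtree to a GPR structure.
fbc_gpr <- function(node, gp_labels) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gp <- local_attr(node, "geneProduct")
    lbl <- gp_labels[[gp]]
    return(if (is.null(lbl)) strip_prefix(gp, "G_") else lbl)
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, fbc_gpr, gp_labels = gp_labels)
  if (name %in% c("and", "or")) {
    if (length(args) == 1L) return(args[[1]])
    return(list(op = name, args = args))
  }
  # geneProductAssociation wrapper: single child
  if (length(args) >= 1L) args[[1]] else NULL
}

#' Load a genome-scale metabolic model from an SBML file
#'
#' Parses SBML Level 2/3 with fbc-package flux bounds and gene products,
#' groups-package subsystems, and the legacy notes dialect. Reactions
#' lacking a subsystem annotation are labelled `"miscellaneous"` (with a
#' warning); exchange status is derived from the stoichiometry (all
#' metabolites on one side of the equation).
#'
#' @param path Path to an SBML `.xml` file.
#' @param pathway_map Optional subsystem to major-pathway mapping (data
#'   frame or path), applied via [apply_pathway_map()].
#' @return A [metabolic_network()].
#' @export
load_network <- function(path, pathway_map = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      rlang::abort(paste0("malformed SBML XML in '", path, "': ",
                          conditionMessage(e)))
    }
  )
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    rlang::abort("malformed SBML: no <model> element")
  }

  # --- species -------------------------------------------------------------
  sp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in%
    c("true", "1")
  metabolites <- tibble::tibble(
    id = strip_prefix(sp_id[!sp_boundary], "M_"),
    compartment = xml2::xml_attr(sp_nodes, "compartment")[!sp_boundary]
  )
  boundary_ids <- sp_id[sp_boundary]

  # --- global parameters (fbc bound references) ----------------------------
  par_nodes <- xml2::xml_find_all(
    model, "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- as.numeric(xml2::xml_attr(par_nodes, "value"))
  names(par_val) <- xml2::xml_attr(par_nodes, "id")

  # --- gene products -------------------------------------------------------
  gp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfGeneProducts']/*")
  gp_labels <- list()
  for (gp in gp_nodes) {
    id <- local_attr(gp, "id")
    lbl <- local_attr(gp, "label")
    gp_labels[[id]] <- if (is.na(lbl)) strip_prefix(id, "G_") else lbl
  }

  # --- reactions -----------------------------------------------------------
  rx_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) rlang::abort("malformed SBML: model has no reactions")

  n <- length(rx_nodes)
  rx_id <- character(n); lb <- rep(NA_real_, n); ub <- rep(NA_real_, n)
  gpr <- character(n); subsystem <- rep(NA_character_, n)
  major <- rep(NA_character_, n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  met_index <- stats::setNames(seq_len(nrow(metabolites)), metabolites$id)

  for (j in seq_len(n)) {
    rxn <- rx_nodes[[j]]
    raw_id <- xml2::xml_attr(rxn, "id")
    rx_id[j] <- strip_prefix(raw_id, "R_")

    lb_ref <- local_attr(rxn, "lowerFluxBound")
    ub_ref <- local_attr(rxn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb[j] <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub[j] <- par_val[[ub_ref]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      # legacy Level 2: kineticLaw local parameters
      for (lp in xml2::xml_find_all(rxn, ".//*[local-name()='parameter' or local-name()='localParameter']")) {
        lp_id <- xml2::xml_attr(lp, "id")
        lp_v <- as.numeric(xml2::xml_attr(lp, "value"))
        if (identical(lp_id, "LOWER_BOUND")) lb[j] <- lp_v
        if (identical(lp_id, "UPPER_BOUND")) ub[j] <- lp_v
      }
    }

    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        rxn, paste0("./*[local-name()='", side,
                    "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (sp %in% boundary_ids) next
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        key <- strip_prefix(sp, "M_")
        if (!key %in% names(met_index)) {
          rlang::abort(paste0("reaction ", rx_id[j],
                              " references unknown species ", sp))
        }
        trip_i <- c(trip_i, met_index[[key]])
        trip_j <- c(trip_j, j)
        trip_x <- c(trip_x, sgn * st)
      }
    }

    gpa <- xml2::xml_find_first(
      rxn, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      gpr[j] <- deparse_gpr(fbc_gpr(gpa, gp_labels))
    } else {
      ga <- notes_field(rxn, "GENE_ASSOCIATION")
      gpr[j] <- if (is.na(ga)) "" else ga
    }
    subsystem[j] <- notes_field(rxn, "SUBSYSTEM")
    major[j] <- notes_field(rxn, "MAJOR_PATHWAY")
  }

  miss <- which(is.na(lb) | is.na(ub))
  if (length(miss)) {
    rlang::abort(paste0("reactions without flux bounds: ",
                        paste(rx_id[miss], collapse = ", ")))
  }

  # --- groups-package subsystems (override notes where present) ------------
  grp_nodes <- xml2::xml_find_all(model, ".//*[local-name()='group']")
  for (grp in grp_nodes) {
    gname <- local_attr(grp, "name")
    if (is.na(gname)) gname <- local_attr(grp, "id")
    members <- xml2::xml_find_all(grp, ".//*[local-name()='member']")
    refs <- vapply(members, function(m) local_attr(m, "idRef"), character(1))
    hit <- match(strip_prefix(refs, "R_"), rx_id)
    subsystem[hit[!is.na(hit)]] <- gname
  }

  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(metabolites), n))
  reactions <- tibble::tibble(
    id = rx_id, lower_bound = lb, upper_bound = ub, gpr = gpr,
    subsystem = subsystem, major_pathway = major
  )
  net <- metabolic_network(reactions, metabolites, S)
  if (!is.null(pathway_map)) net <- apply_pathway_map(net, pathway_map)
  net
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

num_attr <- function(x) sprintf("%.15g", x)

gpr_to_fbc <- function(node, indent) {
  pad <- strrep(" ", indent)
  if (is.character(node)) {
    return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"G_%s\"/>",
                   pad, sid(node)))
  }
  inner <- vapply(node$args, gpr_to_fbc, character(1), indent = indent + 2)
  sprintf("%s<fbc:%s>\n%s\n%s</fbc:%s>",
          pad, node$op, paste(inner, collapse = "\n"), pad, node$op)
}

#' Write a metabolic network to an SBML Level 3 file
#'
#' Emits SBML Level 3 Version 1 with fbc v2 bounds/gene products and
#' groups v1 subsystems; major-pathway labels are stored as reaction notes.
#' Output bytes are deterministic for a given network.
#'
#' @param net A [metabolic_network()].
#' @param path Output file path.
#' @param model_id Model identifier written to the file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path, model_id = "model") {
  stopifnot(inherits(net, "metabolic_network"))
  rx <- net$reactions
  mets <- net$metabolites
  S <- net$stoichiometry
  out <- character(0)
  push <- function(...) out[[length(out) + 1L]] <<- sprintf(...)

  push("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  push(paste0(
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
    " xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\"",
    " xmlns:groups=\"http://www.sbml.org/sbml/level3/version1/groups/version1\"",
    " level=\"3\" version=\"1\" fbc:required=\"false\"",
    " groups:required=\"false\">"))
  push("  <model id=\"%s\" fbc:strict=\"true\">", sid(model_id))

  comps <- unique(c("c", stats::na.omit(mets$compartment)))
  push("    <listOfCompartments>")
  for (cp in comps) {
    push("      <compartment id=\"%s\" constant=\"true\"/>", sid(cp))
  }
  push("    </listOfCompartments>")

  push("    <listOfSpecies>")
  for (k in seq_len(nrow(mets))) {
    cp <- mets$compartment[k]
    if (is.null(cp) || is.na(cp)) cp <- "c"
    push(paste0("      <species id=\"M_%s\" compartment=\"%s\"",
                " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
                " constant=\"false\"/>"),
         sid(mets$id[k]), sid(cp))
  }
  push("    </listOfSpecies>")

  push("    <listOfParameters>")
  for (j in seq_len(nrow(rx))) {
    push("      <parameter id=\"P_lb_%s\" value=\"%s\" constant=\"true\"/>",
         sid(rx$id[j]), num_attr(rx$lower_bound[j]))
    push("      <parameter id=\"P_ub_%s\" value=\"%s\" constant=\"true\"/>",
         sid(rx$id[j]), num_attr(rx$upper_bound[j]))
  }
  push("    </listOfParameters>")

  if (length(net$genes)) {
    push("    <fbc:listOfGeneProducts>")
    for (g in net$genes) {
      push("      <fbc:geneProduct fbc:id=\"G_%s\" fbc:label=\"%s\"/>",
           sid(g), xml_escape(g))
    }
    push("    </fbc:listOfGeneProducts>")
  }

  push("    <listOfReactions>")
  for (j in seq_len(nrow(rx))) {
    rid <- sid(rx$id[j])
    push(paste0("      <reaction id=\"R_%s\" reversible=\"%s\" fast=\"false\"",
                " fbc:lowerFluxBound=\"P_lb_%s\" fbc:upperFluxBound=\"P_ub_%s\">"),
         rid, if (rx$lower_bound[j] < 0) "true" else "false", rid, rid)
    mp <- rx$major_pathway[j]
    if (!is.na(mp) && nzchar(mp)) {
      push("        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>MAJOR_PATHWAY: %s</p></body></notes>",
           xml_escape(mp))
    }
    col <- S[, j]
    nz <- which(col != 0)
    for (side in c(-1, 1)) {
      idx <- nz[sign(col[nz]) == side]
      if (!length(idx)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      push("        <%s>", tag)
      for (k in idx) {
        push(paste0("          <speciesReference species=\"M_%s\"",
                    " stoichiometry=\"%s\" constant=\"true\"/>"),
             sid(mets$id[k]), num_attr(abs(col[k])))
      }
      push("        </%s>", tag)
    }
    node <- parse_gpr(rx$gpr[j], context = rx$id[j])
    if (!is.null(node)) {
      push("        <fbc:geneProductAssociation>")
      push("%s", gpr_to_fbc(node, 10))
      push("        </fbc:geneProductAssociation>")
    }
    push("      </reaction>")
  }
  push("    </listOfReactions>")

  subsystems <- sort(unique(rx$subsystem))
  push("    <groups:listOfGroups>")
  for (k in seq_along(subsystems)) {
    push(paste0("      <groups:group groups:id=\"g%d\"",
                " groups:kind=\"partonomy\" groups:name=\"%s\">"),
         k, xml_escape(subsystems[k]))
    push("        <groups:listOfMembers>")
    for (rid in rx$id[rx$subsystem == subsystems[k]]) {
      push("          <groups:member groups:idRef=\"R_%s\"/>", sid(rid))
    }
    push("        </groups:listOfMembers>")
    push("      </groups:group>")
  }
  push("    </groups:listOfGroups>")
  push("  </model>")
  push("</sbml>")

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
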