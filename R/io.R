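# Dataset and configuration I/O.
#
# Assay CSV dialect: numeric columns `x_uM,rate_uM_per_s[,sd][,replicate]`
# preceded by `# key: value` comment lines carrying the varied species,
# fixed concentrations (`fixed.<species>`) and metadata (`meta.<key>`).
# The writer uses full double precision so datasets round-trip exactly.

#' Write / read an assay dataset as CSV
#'
#' @param dataset an [assay_dataset()].
#' @param path file path.
#' @return `write_assay_csv()` returns `path` invisibly; `read_assay_csv()`
#'   returns an [assay_dataset()].
#' @export
write_assay_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "assay_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# varied_species: ", attr(dataset, "varied_species")),
             con)
  fixed <- attr(dataset, "fixed")
  for (nm in names(fixed))
    writeLines(sprintf("# fixed.%s: %.17g", nm, fixed[[nm]]), con)
  meta <- attr(dataset, "meta")
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.numeric(v) && length(v) > 1L) v <- paste(v, collapse = " ")
    writeLines(paste0("# meta.", nm, ": ", v), con)
  }
  has_sd <- !is.null(dataset$sd)
  header <- paste(c("x_uM", "rate_uM_per_s", if (has_sd) "sd",
                    "replicate"), collapse = ",")
  writeLines(header, con)
  for (i in seq_len(nrow(dataset))) {
    row <- c(sprintf("%.17g", dataset$x[i]),
             sprintf("%.17g", dataset$rate[i]),
             if (has_sd) sprintf("%.17g", dataset$sd[i]),
             sprintf("%d", dataset$replicate[i]))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  kv <- lines[is_comment]
  body <- lines[!is_comment & nzchar(lines)]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  d <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("x_uM", "rate_uM_per_s")
  if (!all(need %in% names(d)))
    stop("assay CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  keys <- sub("^#\\s*([^:]+):.*$", "\\1", kv)
  vals <- sub("^#\\s*[^:]+:\\s*", "", kv)
  varied <- if ("varied_species" %in% keys)
    vals[match("varied_species", keys)] else "x"
  fixed_i <- grepl("^fixed\\.", keys)
  fixed <- stats::setNames(as.numeric(vals[fixed_i]),
                           sub("^fixed\\.", "", keys[fixed_i]))
  meta_i <- grepl("^meta\\.", keys)
  meta <- stats::setNames(as.list(vals[meta_i]),
                          sub("^meta\\.", "", keys[meta_i]))
  num <- suppressWarnings(lapply(meta, as.numeric))
  for (nm in names(meta)) if (!anyNA(num[[nm]])) meta[[nm]] <- num[[nm]]
  assay_dataset(x = d$x_uM, rate = d$rate_uM_per_s, sd = d$sd,
                replicate = if ("replicate" %in% names(d)) d$replicate,
                varied_species = varied, fixed = fixed, meta = meta)
}

#' Write / read a flat key-value parameter configuration
#'
#' Format: one `key = value` pair per line, `#` comments; parameter fields
#' use their [grx_params()] names and species concentrations are prefixed
#' `species.` (e.g. `species.NADPH = 250`). The shipped profiles
#' `"grx1_table1"` / `"grx2_table1"` ([grx_profile()]) can be reproduced
#' with `write_params_config(grx_profile("grx1"), path)`.
#'
#' @param profile list with elements `params` ([grx_params()]) and
#'   `species` (named numeric vector).
#' @param path file path.
#' @return `read_params_config()` returns such a list.
#' @export
write_params_config <- function(profile, path) {
  p <- profile$params
  set_fields <- names(p)[!vapply(p, is.na, TRUE)]
  lines <- c("# grxkin parameter configuration (uM, s units)",
             vapply(set_fields, function(nm)
               sprintf("%s = %.17g", nm, p[[nm]]), ""),
             vapply(names(profile$species), function(nm)
               sprintf("species.%s = %.17g", nm, profile$species[[nm]]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  kv <- .read_kv(path)
  species_i <- grepl("^species\\.", names(kv))
  species <- stats::setNames(as.numeric(kv[species_i]),
                             sub("^species\\.", "", names(kv)[species_i]))
  par_kv <- kv[!species_i]
  bad <- setdiff(names(par_kv), names(.grx_param_units))
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  par_num <- suppressWarnings(lapply(par_kv, as.numeric))
  if (anyNA(par_num))
    stop("non-numeric parameter value in ", path, call. = FALSE)
  list(params = do.call(grx_params, par_num), species = species)
}

# parse `key = value` lines, ignoring comments/blank lines
.read_kv <- function(path) .read_kv_lines(readLines(path))

.read_kv_lines <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines,
                  regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*[^[:space:]]|)[[:space:]]*$",
                          lines))
  bad <- lines[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  stats::setNames(vapply(m, `[[`, "", 3L), vapply(m, `[[`, "", 2L))
}

# --- SBML export -------------------------------------------------------------

# convert an R arithmetic expression to MathML (content markup)
.mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17),
                                   " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  op <- as.character(e[[1L]])
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power",
                stop("unsupported operator in kinetic law: ", op,
                     call. = FALSE))
  args <- vapply(as.list(e)[-1L], .mathml, "")
  paste0("<apply><", tag, "/>", paste(args, collapse = ""), "</apply>")
}

# kinetic-law expression of a reaction as an R call
.rate_expression <- function(rx) {
  r <- rx$rate
  prod_expr <- function(order) {
    terms <- lapply(names(order), function(sp)
      if (order[[sp]] == 1) as.name(sp)
      else call("^", as.name(sp), order[[sp]]))
    Reduce(function(a, b) call("*", a, b), terms)
  }
  if (r$type == "mass_action") {
    fwd <- call("*", as.name(r$k_ref), prod_expr(r$order))
    if (!isTRUE(r$reversible)) return(fwd)
    rev <- call("*", call("/", as.name(r$k_ref), as.name(r$keq_ref)),
                prod_expr(r$reverse_order))
    return(call("-", fwd, rev))
  }
  a <- call("/", as.name(r$A), as.name(r$Ka_ref))
  b <- call("/", as.name(r$B), as.name(r$Kb_ref))
  call("/",
       call("*", call("*", as.name(r$kcat_ref), as.name(r$E_ref)),
            call("*", a, b)),
       call("*", call("+", 1, a), call("+", 1, b)))
}

#' Export a model as SBML Level 3
#'
#' Serialises species (clamped species as boundary conditions with
#' `constant="true"`), global parameters and reactions with explicit
#' MathML kinetic laws. Import is not supported.
#'
#' @param model a `grx_model`.
#' @param path output file path (`.xml`).
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "grx_model") {
  stopifnot(inherits(model, "grx_model"))
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
           'level="3" version="2">'),
    sprintf('  <model id="%s" substanceUnits="micromole" ', esc(model_id)),
    '         timeUnits="second" extentUnits="micromole">',
    '    <listOfCompartments>',
    '      <compartment id="cell" spatialDimensions="3" size="1"',
    '                   constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    clamped <- s$role == "clamped"
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" compartment="cell" ',
             'initialConcentration="%.17g" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="%s" constant="%s"/>'),
      s$name, s$conc, tolower(clamped), tolower(clamped)))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  used <- unique(unlist(lapply(model$reactions, function(rx) {
    r <- rx$rate
    c(r$k_ref, r$keq_ref, r$kcat_ref, r$E_ref, r$Ka_ref, r$Kb_ref)
  })))
  for (nm in used)
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%.17g" constant="true"/>',
      nm, model$params[[nm]]))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (rx in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s">', rx$id,
      tolower(isTRUE(rx$rate$reversible))))
    reag <- rx$stoich[rx$stoich < 0]
    prod <- rx$stoich[rx$stoich > 0]
    if (length(reag)) {
      lines <- c(lines, '        <listOfReactants>')
      for (nm in names(reag))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%g" constant="true"/>'), nm, -reag[[nm]]))
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>')
      for (nm in names(prod))
        lines <- c(lines, sprintf(
          paste0('          <speciesReference species="%s" ',
                 'stoichiometry="%g" constant="true"/>'), nm, prod[[nm]]))
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines,
               '        <kineticLaw>',
               paste0('          <math xmlns="http://www.w3.org/1998/',
                      'Math/MathML">'),
               paste0('            ', .mathml(.rate_expression(rx))),
               '          </math>',
               '        </kineticLaw>',
               '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  # validate well-formedness before returning
  invisible({
    xml2::read_xml(path)
    path
  })
}
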