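#' Read an annotated model document
#'
#' Auto-detects the format: files starting with `<` are parsed as the
#' CellML-subset XML (variables with initial values plus RDF annotation
#' blocks); anything else as the neutral structured text format.
#'
#' @section Neutral text format:
#' Line-oriented; `#` starts a comment. Directives:
#' \preformatted{
#' model <id>
#' species <name> [chemostat] q0=<num> [Kq=<num>] [units=<text>]
#'         [annot=<term;term;...>]
#' reaction <name> : <side> -> <side> [kplus=<num>] [kminus=<num>]
#'          [kappa=<num>] [vmax=<num>] [km=<num>]
#' }
#' A side is `2 A + B` style (integer coefficients, `+` separators). A
#' reaction with `kplus` and `kminus` is reversible mass action, with
#' `kplus` alone irreversible, with `vmax`/`km` irreversible
#' Michaelis-Menten, and with `kappa` already in bond-graph form.
#'
#' @section CellML subset:
#' `<variable name="q0_X" initial_value="..." units="..."/>` and
#' `Kq_X` variables carry values; `<rdf:Description rdf:about="#q0_X">`
#' blocks with `<bqbiol:is rdf:resource="term"/>` children carry the
#' annotation set of species X. The term `BG:chemostat` marks a chemostat.
#' Reaction structure is not encoded; it comes from a symbolic template.
#'
#' @param path file path.
#' @return an object of class `bgModelDocument`: a list with `name`,
#'   `species`, `reactions`, `format`, `path`.
#' @export
readModelDocument <- function(path) {
  if (!file.exists(path))
    bgStop("bgFormatError", "file not found: %s", path)
  head <- readChar(path, nchars = 200)
  if (grepl("^\\s*<", head)) readCellMLSubset(path)
  else readNeutralFormat(path)
}

parseNum <- function(x, what, line) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    bgStop("bgFormatError", "line %d: %s is not a number ('%s')", line, what, x)
  v
}

parseSide <- function(text, line) {
  parts <- trimws(strsplit(text, "\\+")[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts))
    bgStop("bgFormatError", "line %d: empty reaction side", line)
  st <- numeric()
  for (p in parts) {
    tok <- strsplit(p, "\\s+")[[1]]
    if (length(tok) == 1) st[tok] <- 1
    else if (length(tok) == 2)
      st[tok[2]] <- parseNum(tok[1], "stoichiometry", line)
    else bgStop("bgFormatError", "line %d: cannot parse term '%s'", line, p)
  }
  st
}

readNeutralFormat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  doc <- list(name = NULL, species = list(), reactions = list(),
              format = "neutral", path = path)
  for (i in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[i])
    line <- trimws(raw)
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    kw <- tok[1]
    if (kw == "model") {
      if (length(tok) < 2)
        bgStop("bgFormatError", "line %d: model needs an id", i)
      doc$name <- tok[2]
    } else if (kw == "species") {
      if (length(tok) < 2)
        bgStop("bgFormatError", "line %d: species needs a name", i)
      rec <- list(name = tok[2], chemostat = FALSE, q0 = NA_real_,
                  Kq = NA_real_, units = NA_character_,
                  annotations = character())
      for (opt in tok[-(1:2)]) {
        if (opt == "chemostat") { rec$chemostat <- TRUE; next }
        kv <- strsplit(opt, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2)
          bgStop("bgFormatError", "line %d: cannot parse option '%s'", i, opt)
        switch(kv[1],
          q0 = rec$q0 <- parseNum(kv[2], "q0", i),
          Kq = rec$Kq <- parseNum(kv[2], "Kq", i),
          units = rec$units <- kv[2],
          annot = rec$annotations <- strsplit(kv[2], ";", fixed = TRUE)[[1]],
          bgStop("bgFormatError", "line %d: unknown species option '%s'",
                 i, kv[1]))
      }
      doc$species[[rec$name]] <- rec
    } else if (kw == "reaction") {
      m <- regmatches(line,
        regexec("^reaction\\s+(\\S+)\\s*:\\s*(.+?)\\s*(<->|->)\\s*(.+)$", line))[[1]]
      if (!length(m))
        bgStop("bgFormatError", "line %d: cannot parse reaction", i)
      name <- m[2]
      rhsAll <- m[5]
      # trailing key=value options belong to the reaction, not the side
      rhsTok <- strsplit(rhsAll, "\\s+")[[1]]
      isOpt <- grepl("=", rhsTok, fixed = TRUE)
      sideTok <- rhsTok[!isOpt]
      opts <- rhsTok[isOpt]
      rec <- list(name = name,
                  reactants = parseSide(m[3], i),
                  products = parseSide(paste(sideTok, collapse = " "), i),
                  kplus = NA_real_, kminus = NA_real_, kappa = NA_real_,
                  vmax = NA_real_, km = NA_real_)
      for (opt in opts) {
        kv <- strsplit(opt, "=", fixed = TRUE)[[1]]
        switch(kv[1],
          kplus = rec$kplus <- parseNum(kv[2], "kplus", i),
          kminus = rec$kminus <- parseNum(kv[2], "kminus", i),
          kappa = rec$kappa <- parseNum(kv[2], "kappa", i),
          vmax = rec$vmax <- parseNum(kv[2], "vmax", i),
          km = rec$km <- parseNum(kv[2], "km", i),
          bgStop("bgFormatError", "line %d: unknown reaction option '%s'",
                 i, kv[1]))
      }
      doc$reactions[[name]] <- rec
    } else {
      bgStop("bgFormatError", "line %d: unknown directive '%s'", i, kw)
    }
  }
  undeclared <- setdiff(
    unique(unlist(lapply(doc$reactions, function(r)
      c(names(r$reactants), names(r$products))))),
    names(doc$species))
  if (length(undeclared))
    bgStop("bgFormatError", "%s: reactions reference undeclared species: %s",
           path, paste(undeclared, collapse = ", "))
  class(doc) <- "bgModelDocument"
  doc
}

readCellMLSubset <- function(path) {
  xml <- tryCatch(xml2::read_xml(path), error = function(e)
    bgStop("bgParseError", "XML parse error in %s: %s", path,
           conditionMessage(e)))
  ns <- xml2::xml_ns(xml)
  vars <- xml2::xml_find_all(xml, ".//*[local-name() = 'variable']")
  descr <- xml2::xml_find_all(xml, ".//*[local-name() = 'Description']")
  annotationsOf <- new.env(parent = emptyenv())
  for (d in descr) {
    about <- sub("^#", "", xml2::xml_attr(d, "about"))
    terms <- xml2::xml_attr(
      xml2::xml_find_all(d, ".//*[local-name() = 'is']"), "resource")
    assign(about, terms, envir = annotationsOf)
  }
  species <- list()
  for (v in vars) {
    nm <- xml2::xml_attr(v, "name")
    val <- suppressWarnings(as.numeric(xml2::xml_attr(v, "initial_value")))
    units <- xml2::xml_attr(v, "units")
    field <- sub("_.*$", "", nm)
    spName <- sub("^[^_]*_", "", nm)
    if (!(field %in% c("q0", "Kq")) || !nzchar(spName)) next
    if (is.null(species[[spName]]))
      species[[spName]] <- list(name = spName, chemostat = FALSE,
                                q0 = NA_real_, Kq = NA_real_,
                                units = NA_character_,
                                annotations = character())
    species[[spName]][[if (field == "q0") "q0" else "Kq"]] <- val
    if (!is.na(units) && field == "q0") species[[spName]]$units <- units
    terms <- mget(nm, envir = annotationsOf, ifnotfound = list(character()))[[1]]
    species[[spName]]$annotations <-
      sort(unique(c(species[[spName]]$annotations, terms)))
    if ("BG:chemostat" %in% species[[spName]]$annotations)
      species[[spName]]$chemostat <- TRUE
  }
  doc <- list(name = xml2::xml_attr(xml, "name"), species = species,
              reactions = list(), format = "cellml", path = path)
  class(doc) <- "bgModelDocument"
  doc
}

#' Extract annotated entities from a model document
#'
#' One entity per species record; values (Kq, q0, units text) are carried
#' along. Species without annotations are included with an empty term set
#' (and thereby excluded from matching); a document with no annotations at
#' all triggers a warning.
#'
#' @param doc a `bgModelDocument` from [readModelDocument()], or a path.
#' @param module module id to stamp on the entities (defaults to the
#'   document's model name, then its file name).
#' @return list of [AnnotatedEntity-class].
#' @export
extractAnnotations <- function(doc, module = NULL) {
  if (is.character(doc)) doc <- readModelDocument(doc)
  stopifnot(inherits(doc, "bgModelDocument"))
  if (is.null(module))
    module <- if (!is.null(doc$name)) doc$name
      else tools::file_path_sans_ext(basename(doc$path))
  ents <- lapply(doc$species, function(s)
    annotatedEntity(module, s$name,
                    if (isTRUE(s$chemostat)) "chemostat" else "species",
                    s$annotations,
                    list(Kq = s$Kq, q0 = s$q0, units = s$units)))
  ents <- unname(ents)
  if (!any(vlapply(ents, function(e) length(e@annotations) > 0)))
    bgWarn("bgNoAnnotationWarning",
           "document '%s' carries no annotations; nothing is matchable",
           module)
  ents
}

#' Build a bond-graph network from a document
#'
#' Requires the document's reactions to carry bond-graph `kappa` values (or
#' none, for a symbolic structure with unset parameters).
#'
#' @param doc a `bgModelDocument`.
#' @param ctx a [ThermoContext-class].
#' @return a [BondGraphNetwork-class].
#' @export
documentNetwork <- function(doc, ctx = thermoContext()) {
  stopifnot(inherits(doc, "bgModelDocument"))
  species <- lapply(doc$species, function(s)
    speciesComponent(s$name, Kq = s$Kq, q0 = s$q0, chemostat = s$chemostat,
                     annotations = s$annotations))
  reactions <- lapply(doc$reactions, function(r)
    reactionComponent(r$name, r$reactants, r$products, kappa = r$kappa))
  buildNetwork(unname(species), unname(reactions), ctx)
}

#' Kinetic reactions of a document
#'
#' @param doc a `bgModelDocument`.
#' @return list of [KineticReaction-class] for every reaction carrying
#'   kinetic constants (kplus/kminus or vmax/km).
#' @export
documentKinetics <- function(doc) {
  stopifnot(inherits(doc, "bgModelDocument"))
  recs <- Filter(function(r) !is.na(r$kplus) || !is.na(r$vmax), doc$reactions)
  unname(lapply(recs, function(r)
    kineticReaction(r$name, r$reactants, r$products, kPlus = r$kplus,
                    kMinus = r$kminus, Vmax = r$vmax, Km = r$km)))
}

#' @export
print.bgModelDocument <- function(x, ...) {
  cat(sprintf("bgModelDocument '%s' (%s): %d species, %d reactions\n",
              if (is.null(x$name)) "?" else x$name, x$format,
              length(x$species), length(x$reactions)))
  invisible(x)
}
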