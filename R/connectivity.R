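#' Connectivity-matrix view of a bond-graph network
#'
#' `toConnectivityMatrix()` renders the canonical wiring as a labelled
#' symmetric binary matrix with a 1 wherever two elements share a bond.
#' `fromConnectivityMatrix()` inverts it: given the component definitions it
#' rebuilds the network and verifies that the canonical wiring reproduces
#' the matrix exactly (round-trip identity).
#'
#' @param network a [BondGraphNetwork-class].
#' @return a [ConnectivityMatrix-class].
#' @examples
#' net <- buildNetwork(
#'   list(speciesComponent("A", 1, 2), speciesComponent("B", 1, 0)),
#'   list(reactionComponent("r1", c(A = 1), c(B = 1), kappa = 1)))
#' cm <- toConnectivityMatrix(net)
#' cm@matrix
#' @aliases toConnectivityMatrix
#' @export
setMethod("toConnectivityMatrix", "BondGraphNetwork", function(network) {
  w <- networkWiring(network)
  connectivityMatrix(w$labels, w$bonds)
})

#' Construct a connectivity matrix from labels and bonds
#'
#' @param labels ordered element identifiers.
#' @param bonds two-column character matrix of bonded label pairs.
#' @rdname toConnectivityMatrix
#' @export
connectivityMatrix <- function(labels, bonds = matrix(character(), 0, 2)) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (length(bonds)) {
    bonds <- matrix(as.character(bonds), ncol = 2)
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, 1]; b <- bonds[i, 2]
      if (!(a %in% labels) || !(b %in% labels))
        bgStop("bgLookupError", "bond endpoint not among labels: %s",
               paste(setdiff(c(a, b), labels), collapse = ", "))
      if (a == b)
        bgStop("bgValidationError", "self-bond on '%s' is not allowed", a)
      m[a, b] <- 1
      m[b, a] <- 1
    }
  }
  new("ConnectivityMatrix", labels = labels, matrix = m)
}

#' @param cm a [ConnectivityMatrix-class].
#' @param species,reactions component definitions for every matrix label.
#' @param ctx a [ThermoContext-class].
#' @rdname toConnectivityMatrix
#' @export
fromConnectivityMatrix <- function(cm, species, reactions,
                                   ctx = thermoContext()) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  validObject(cm)
  net <- buildNetwork(species, reactions, ctx)
  ref <- toConnectivityMatrix(net)
  missing <- setdiff(cm@labels, ref@labels)
  if (length(missing))
    bgStop("bgLookupError", "no component definition for label(s): %s",
           paste(missing, collapse = ", "))
  extra <- setdiff(ref@labels, cm@labels)
  if (length(extra))
    bgStop("bgFormatError", "matrix is missing element(s): %s",
           paste(extra, collapse = ", "))
  reordered <- ref@matrix[cm@labels, cm@labels]
  if (!isTRUE(all.equal(reordered, cm@matrix, check.attributes = FALSE)))
    bgStop("bgFormatError",
           "matrix bonds do not match the canonical wiring of the definitions")
  net
}

#' Edit a connectivity matrix
#'
#' Deletes the rows and columns of `remove` and then sets the symmetric
#' entry pair to 1 for every row of `addBonds`. Adding an existing bond is
#' idempotent; a self-bond is an error.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param remove labels whose rows/columns are deleted.
#' @param addBonds two-column character matrix (or length-2 vector) of label
#'   pairs to bond.
#' @return the edited [ConnectivityMatrix-class].
#' @export
editMatrix <- function(cm, remove = character(),
                       addBonds = matrix(character(), 0, 2)) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  labels <- cm@labels
  unknown <- setdiff(remove, labels)
  if (length(unknown))
    bgStop("bgLookupError", "cannot remove unknown label(s): %s",
           paste(unknown, collapse = ", "))
  keep <- setdiff(labels, remove)
  m <- cm@matrix[keep, keep, drop = FALSE]
  if (length(addBonds)) {
    addBonds <- matrix(as.character(addBonds), ncol = 2)
    for (i in seq_len(nrow(addBonds))) {
      a <- addBonds[i, 1]; b <- addBonds[i, 2]
      unknown <- setdiff(c(a, b), keep)
      if (length(unknown))
        bgStop("bgLookupError", "bond endpoint not present: %s",
               paste(unknown, collapse = ", "))
      if (a == b)
        bgStop("bgValidationError", "self-bond on '%s' is not allowed", a)
      m[a, b] <- 1
      m[b, a] <- 1
    }
  }
  new("ConnectivityMatrix", labels = keep, matrix = m)
}

# block-diagonal stack of connectivity matrices; labels are prefixed
# "<module>:" so assembly never collides.
blockDiagonalMatrix <- function(cms, prefixes = names(cms)) {
  stopifnot(length(cms) == length(prefixes))
  labels <- unlist(lapply(seq_along(cms), function(i)
    paste0(prefixes[[i]], ":", cms[[i]]@labels)))
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  off <- 0
  for (i in seq_along(cms)) {
    k <- length(cms[[i]]@labels)
    idx <- off + seq_len(k)
    m[idx, idx] <- cms[[i]]@matrix
    off <- off + k
  }
  new("ConnectivityMatrix", labels = labels, matrix = m)
}

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix: %d elements, %d bonds\n",
              length(object@labels), sum(object@matrix) / 2))
})

#' Read and write connectivity matrices as CSV
#'
#' First row and first column hold the element labels; body entries are 0/1.
#' Reading validates symmetry and binarity and reports the offending cells.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path CSV file path.
#' @return `readConnectivityCSV()` returns a [ConnectivityMatrix-class];
#'   `writeConnectivityCSV()` returns `path` invisibly.
#' @export
writeConnectivityCSV <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  df <- data.frame(label = cm@labels, cm@matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeConnectivityCSV
#' @export
readConnectivityCSV <- function(path) {
  if (!file.exists(path))
    bgStop("bgFormatError", "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1)
    bgStop("bgFormatError", "empty connectivity CSV: %s", path)
  labels <- as.character(df[[1]])
  body <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(body), labels))
    bgStop("bgFormatError",
           "row labels and column labels disagree in %s", path)
  storage.mode(body) <- "numeric"
  if (any(is.na(body)) || !all(body %in% c(0, 1))) {
    bad <- which(is.na(body) | !(body %in% c(0, 1)), arr.ind = TRUE)[1, ]
    bgStop("bgFormatError", "non-binary entry at (%s, %s) in %s",
           labels[bad[1]], labels[bad[2]], path)
  }
  asym <- which(body != t(body), arr.ind = TRUE)
  if (nrow(asym)) {
    bgStop("bgFormatError",
           "asymmetric entries: (%s, %s) differs from (%s, %s) in %s",
           labels[asym[1, 1]], labels[asym[1, 2]],
           labels[asym[1, 2]], labels[asym[1, 1]], path)
  }
  dimnames(body) <- list(labels, labels)
  new("ConnectivityMatrix", labels = labels, matrix = body)
}
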