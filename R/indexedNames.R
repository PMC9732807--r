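# The indexed-group convention: repeatable HDF5 groups share a base name and
# carry 1-based decimal suffixes with no zero padding ("stim1", "stim2", ...).
# A bare base name (no digits) is legal only for a singleton collection.

#' Parse an indexed-group name
#'
#' Splits the maximal run of trailing decimal digits off a group or dataset
#' name. Indices start at 1 and are written without zero padding, so a
#' trailing `0` or a padded index such as `"stim01"` is rejected.
#'
#' @param name Group or dataset name, e.g. `"stim3"`.
#' @return List with elements `base` (string) and `index` (positive integer,
#'   or `NA` for a bare name without digits).
#' @examples
#' parseIndexedName("stim3")            # base "stim", index 3
#' parseIndexedName("probe")            # base "probe", index NA
#' parseIndexedName("measurementList12")
#' @export
parseIndexedName <- function(name) {
    res <- .parseIndexedNameQuiet(name)
    if (!res$ok) stop(res$problem, call. = FALSE)
    res[c("base", "index")]
}

# non-stopping variant used by the permissive reader
.parseIndexedNameQuiet <- function(name) {
    if (!is.character(name) || length(name) != 1L || !nzchar(name))
        return(list(ok = FALSE, base = NA_character_, index = NA_integer_,
                    problem = "name must be a non-empty string"))
    digits <- regmatches(name, regexpr("[0-9]+$", name))
    if (!length(digits))
        return(list(ok = TRUE, base = name, index = NA_integer_, problem = NA))
    base <- substr(name, 1L, nchar(name) - nchar(digits))
    if (substr(digits, 1L, 1L) == "0")
        return(list(ok = FALSE, base = base, index = NA_integer_,
                    problem = sprintf(
                        "index in '%s' is zero or zero-padded; indices are 1-based decimals without padding",
                        name)))
    idx <- suppressWarnings(as.integer(digits))
    if (is.na(idx))
        return(list(ok = FALSE, base = base, index = NA_integer_,
                    problem = sprintf("index in '%s' overflows", name)))
    list(ok = TRUE, base = base, index = idx, problem = NA)
}

#' Render an indexed-group name
#'
#' Inverse of [parseIndexedName()]: appends the decimal index to the base, or
#' returns the bare base when `index` is `NA` (singleton form).
#'
#' @param base Base name, e.g. `"stim"`.
#' @param index Positive integer, or `NA` for the bare singleton form.
#' @return The rendered name.
#' @export
renderIndexedName <- function(base, index = NA) {
    stopifnot(is.character(base), length(base) == 1L, nzchar(base))
    if (is.na(index)) return(base)
    index <- as.integer(index)
    if (index < 1L) stop("indices are 1-based", call. = FALSE)
    paste0(base, index)
}

# Gather an indexed collection from a vector of child names. Returns member
# names ordered by numeric index plus any findings about naming/contiguity
# discovered along the way (zero-padding, bare+indexed collisions, gaps).
.collectIndexed <- function(childNames, base, parentPath) {
    fnd <- list()
    members <- character(0)
    indices <- integer(0)
    bare <- NULL
    pat <- paste0("^", base, "[0-9]*$")
    for (nm in childNames[grepl(pat, childNames)]) {
        p <- .parseIndexedNameQuiet(nm)
        if (!p$ok) {
            fnd[[length(fnd) + 1L]] <- .finding(
                "BAD_INDEX_NAME", "ERROR", .joinPath(parentPath, nm),
                p$problem, "indexed-groups")
            next
        }
        if (is.na(p$index)) bare <- nm
        else { members <- c(members, nm); indices <- c(indices, p$index) }
    }
    if (!is.null(bare) && length(members)) {
        fnd[[length(fnd) + 1L]] <- .finding(
            "BAD_INDEX_NAME", "ERROR", .joinPath(parentPath, bare),
            sprintf("bare name '%s' coexists with indexed members of the same collection",
                    bare), "indexed-groups")
        bare <- NULL
    }
    if (!is.null(bare)) { members <- bare; indices <- 1L }
    if (length(members)) {
        ord <- order(indices)
        members <- members[ord]; indices <- indices[ord]
        if (anyDuplicated(indices)) {
            dup <- indices[duplicated(indices)][1L]
            fnd[[length(fnd) + 1L]] <- .finding(
                "BAD_INDEX_NAME", "ERROR",
                .joinPath(parentPath, paste0(base, dup)),
                sprintf("duplicate index %d in '%s' collection", dup, base),
                "indexed-groups")
        } else if (!identical(indices, seq_along(indices))) {
            fnd[[length(fnd) + 1L]] <- .finding(
                "NONCONTIGUOUS_INDEX", "ERROR", .joinPath(parentPath, base),
                sprintf("'%s' collection has indices {%s}; indexed groups must be numbered 1..%d without gaps",
                        base, paste(indices, collapse = ", "), length(indices)),
                "indexed-groups")
        }
    }
    list(members = members, findings = fnd)
}

.joinPath <- function(parent, child) {
    if (parent == "/") paste0("/", child) else paste0(parent, "/", child)
}
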