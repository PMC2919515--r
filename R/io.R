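# File formats: points CSV (cell_id,x,y), outlines CSV
# (cell_id,object_id,vertex_index,x,y) or GeoJSON, binary masks
# (PNG/TIFF), JSON serialisation of potentials and scenarios.

.require_cols <- function(tab, cols, path) {
    miss <- setdiff(cols, names(tab))
    if (length(miss))
        .stopf("file '%s': missing required column(s): %s", path,
               paste(miss, collapse = ", "))
}

#' Read / write point objects
#'
#' CSV with header \code{cell_id,x,y}; one row per point.
#'
#' @param path CSV file path.
#' @return \code{readPointsCSV}: named list (one matrix of points per
#'   cell); \code{writePointsCSV}: invisibly, the path.
#' @export
readPointsCSV <- function(path) {
    tab <- utils::read.csv(path)
    .require_cols(tab, c("cell_id", "x", "y"), path)
    bad <- which(!is.finite(tab$x) | !is.finite(tab$y))
    if (length(bad))
        .stopf("file '%s', line %d: non-numeric x/y", path, bad[1L] + 1L)
    lapply(split(tab, tab$cell_id), function(s) cbind(x = s$x, y = s$y))
}

#' @rdname readPointsCSV
#' @param points named list of point matrices (one per cell).
#' @export
writePointsCSV <- function(points, path) {
    tab <- do.call(rbind, lapply(names(points), function(k)
        data.frame(cell_id = k, x = points[[k]][, 1L], y = points[[k]][, 2L])))
    utils::write.csv(tab, path, row.names = FALSE)
    invisible(path)
}

#' Read / write outline objects
#'
#' CSV with header \code{cell_id,object_id,vertex_index,x,y}; vertices
#' are ordered by \code{vertex_index} and the ring is closed implicitly.
#' GeoJSON FeatureCollections of Polygons (first ring only, cell label in
#' the \code{cell_id} property) are also supported.
#'
#' @param path file path.
#' @return named list (per cell) of lists of polygon vertex matrices.
#' @export
readOutlinesCSV <- function(path) {
    tab <- utils::read.csv(path)
    .require_cols(tab, c("cell_id", "object_id", "vertex_index", "x", "y"), path)
    lapply(split(tab, tab$cell_id), function(s)
        lapply(split(s, s$object_id), function(o) {
            o <- o[order(o$vertex_index), ]
            v <- cbind(x = o$x, y = o$y)
            if (nrow(unique(round(v, 9L))) < 3L)
                .stopf("file '%s': degenerate outline (cell %s, object %s): fewer than 3 distinct vertices",
                       path, o$cell_id[1L], o$object_id[1L])
            v
        }))
}

#' @rdname readOutlinesCSV
#' @param outlines named list (per cell) of lists of polygon matrices.
#' @export
writeOutlinesCSV <- function(outlines, path) {
    rows <- list()
    for (k in names(outlines))
        for (j in seq_along(outlines[[k]])) {
            v <- outlines[[k]][[j]]
            rows[[length(rows) + 1L]] <-
                data.frame(cell_id = k, object_id = j,
                           vertex_index = seq_len(nrow(v)),
                           x = v[, 1L], y = v[, 2L])
        }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname readOutlinesCSV
#' @export
readOutlinesGeoJSON <- function(path) {
    gj <- jsonlite::read_json(path)
    if (!identical(gj$type, "FeatureCollection"))
        .stopf("file '%s': expected a GeoJSON FeatureCollection", path)
    out <- list()
    for (ft in gj$features) {
        if (!identical(ft$geometry$type, "Polygon")) next
        k <- as.character(ft$properties$cell_id %||% "cell")
        ring <- ft$geometry$coordinates[[1L]]
        v <- do.call(rbind, lapply(ring, function(p)
            c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
        colnames(v) <- c("x", "y")
        out[[k]] <- c(out[[k]], list(v))
    }
    out
}

#' Read / write a binary domain mask
#'
#' Single-channel PNG or TIFF; nonzero pixels are inside the domain.
#'
#' @param path image path (.png or .tif/.tiff).
#' @return \code{readMask}: a [CellDomain-class] of type mask.
#' @export
readMask <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        .stopf("file '%s': unsupported mask format '%s' (use PNG or TIFF)",
               path, ext))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    maskDomain(img > 0)
}

#' @rdname readMask
#' @param domain a mask-type [CellDomain-class].
#' @export
writeMask <- function(domain, path) {
    stopifnot(is(domain, "CellDomain"), domain@type == "mask")
    img <- matrix(as.numeric(domain@mask), nrow(domain@mask))
    ext <- tolower(tools::file_ext(path))
    switch(ext,
        png = png::writePNG(img, path),
        tif = ,
        tiff = tiff::writeTIFF(img, path),
        .stopf("unsupported mask format '%s'", ext))
    invisible(path)
}

#' Serialise a potential to / from JSON
#'
#' Parametric potentials: \code{{family, epsilon, sigma, t}};
#' non-parametric: \code{{support_points, weights, h, s}}.
#'
#' @param pot a potential object.
#' @param path optional file path (returns a JSON string when NULL).
#' @export
potentialToJSON <- function(pot, path = NULL) {
    x <- if (is(pot, "InteractionPotential"))
        list(family = pot@family, epsilon = pot@epsilon,
             sigma = pot@sigma, t = pot@t)
    else
        list(support_points = pot@supportPoints, weights = pot@weights,
             h = pot@spacing, s = pot@smoothness)
    if (is.null(path))
        jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
    else {
        jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
        invisible(path)
    }
}

#' @rdname potentialToJSON
#' @param json JSON string or file path.
#' @export
potentialFromJSON <- function(json) {
    x <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
    if (!is.null(x$family))
        interactionPotential(x$family, x$epsilon, x$sigma, x$t)
    else
        nonparametricPotential(x$support_points, x$weights, x$h,
                               x$s %||% NA_real_)
}

#' Assemble per-cell object sets from files
#'
#' Reads points, optional outlines and an optional domain (mask image or
#' rectangle), merges them by cell id, validates (degenerate outlines are
#' errors; objects outside the domain are reported), and returns one
#' [ObjectSet-class] per cell plus a validation report.
#'
#' @param points path of the points CSV.
#' @param outlines optional path of the outlines CSV or GeoJSON.
#' @param mask optional path of a mask image defining the domain.
#' @param domainSize optional width/height of a rectangular domain
#'   (ignored when \code{mask} is given).
#' @return list with \code{cells} (named list of ObjectSets) and
#'   \code{report} (character vector of validation messages).
#' @export
readObjects <- function(points, outlines = NULL, mask = NULL,
                        domainSize = NULL) {
    pts <- readPointsCSV(points)
    outl <- if (is.null(outlines)) list()
            else if (tolower(tools::file_ext(outlines)) %in% c("json", "geojson"))
                readOutlinesGeoJSON(outlines)
            else readOutlinesCSV(outlines)
    dom <- if (!is.null(mask)) readMask(mask)
           else if (!is.null(domainSize))
               rectangleDomain(domainSize[1L], domainSize[2L])
           else NULL
    report <- character(0)
    ids <- union(names(pts), names(outl))
    cells <- list()
    for (k in ids) {
        X <- pts[[k]] %||% matrix(numeric(0), 0, 2)
        Ypolys <- lapply(outl[[k]] %||% list(), identity)
        if (!is.null(dom)) {
            allv <- rbind(X, do.call(rbind, Ypolys))
            out <- if (nrow(allv)) sum(!.in_domain(dom, allv)) else 0L
            if (out > 0) {
                report <- c(report, sprintf(
                    "cell %s: %d object vertex/point(s) outside the domain", k, out))
                next
            }
        }
        cells[[k]] <- objectSet(X, Ypolys, cellId = k, domain = dom)
    }
    list(cells = cells, report = report)
}

#' Write / read a synthetic scenario directory
#'
#' Plain-text serialisation of a [CellData-class]: points.csv,
#' outlines.csv, domain.json (polygon domains) or mask.png, q.csv/q.json,
#' and a truth.json sidecar with the generating parameters.
#'
#' @param cd a [CellData-class] with objects attached.
#' @param dir output directory (created if needed).
#' @export
writeScenario <- function(cd, dir) {
    stopifnot(is(cd, "CellData"), !is.null(cd@objects))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    objs <- cd@objects
    writePointsCSV(stats::setNames(list(objs@X), cd@cellId),
                   file.path(dir, "points.csv"))
    writeOutlinesCSV(stats::setNames(list(objs@Y), cd@cellId),
                     file.path(dir, "outlines.csv"))
    dom <- objs@domain
    if (!is.null(dom)) {
        if (dom@type == "mask") writeMask(dom, file.path(dir, "mask.png"))
        else jsonlite::write_json(
            list(type = "polygon",
                 x = dom@polygon[, 1L], y = dom@polygon[, 2L]),
            file.path(dir, "domain.json"), digits = NA)
    }
    writeStateDensity(cd@q, file.path(dir, "q.csv"), file.path(dir, "q.json"))
    truth <- list(cell_id = cd@cellId,
                  covariates = cd@covariates)
    if (!is.null(cd@truth$spec)) {
        sp <- cd@truth$spec
        truth$scenario <- list(domain_size = sp$domainSize, M = sp$M,
                               R = sp$R, arrangement = sp$arrangement,
                               N = sp$N, seed = sp$seed)
    }
    if (!is.null(cd@truth$potential))
        truth$potential <- jsonlite::fromJSON(
            potentialToJSON(cd@truth$potential))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname writeScenario
#' @return \code{readScenario}: a [CellData-class].
#' @export
readScenario <- function(dir) {
    pts <- readPointsCSV(file.path(dir, "points.csv"))
    outl <- readOutlinesCSV(file.path(dir, "outlines.csv"))
    k <- names(pts)[1L]
    dom <- if (file.exists(file.path(dir, "mask.png")))
        readMask(file.path(dir, "mask.png"))
    else if (file.exists(file.path(dir, "domain.json"))) {
        dj <- jsonlite::read_json(file.path(dir, "domain.json"),
                                  simplifyVector = TRUE)
        polygonDomain(cbind(dj$x, dj$y))
    } else NULL
    objs <- objectSet(pts[[k]], outl[[k]] %||% list(), cellId = k,
                      domain = dom)
    q <- readStateDensity(file.path(dir, "q.csv"), file.path(dir, "q.json"))
    truth <- if (file.exists(file.path(dir, "truth.json")))
        jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE) else list()
    tp <- if (!is.null(truth$potential))
        interactionPotential(truth$potential$family, truth$potential$epsilon,
                             truth$potential$sigma, truth$potential$t)
    else NULL
    cellData(nnDistances(objs), q, cellId = k,
             covariates = as.list(truth$covariates %||% list()),
             truth = list(potential = tp), objects = objs)
}
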