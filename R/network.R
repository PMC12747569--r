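#' Centerline network container
#'
#' A graph of 3D centerline points with maximal-inscribed-sphere radii,
#' branch ids, the set of endpoints (graph degree 1) and the inlet point.
#'
#' @param points n x 3 matrix of coordinates (mm).
#' @param radius numeric length-n inscribed-sphere radii (mm, > 0).
#' @param edges m x 2 integer matrix of point-index pairs.
#' @param branch_id integer length-n branch identifier per point.
#' @param endpoints integer indices of degree-1 points.
#' @param inlet integer index of the inlet endpoint.
#' @return a `centerline_network`.
#' @export
centerline_network <- function(points, radius, edges, branch_id = NULL,
                               endpoints = NULL, inlet = NULL) {
  points <- as.matrix(points); storage.mode(points) <- "double"
  edges <- as.matrix(edges); storage.mode(edges) <- "integer"
  if (any(radius <= 0)) stop("all inscribed radii must be positive")
  deg <- tabulate(as.vector(edges), nbins = nrow(points))
  if (is.null(endpoints) || !length(endpoints)) endpoints <- which(deg == 1L)
  if (!all(deg[endpoints] == 1L)) stop("endpoints must have graph degree 1")
  if (!is.null(inlet) && length(inlet) && !(inlet %in% endpoints))
    stop("inlet must be one of the endpoints")
  if (!length(inlet)) inlet <- NULL
  structure(list(points = points, radius = as.numeric(radius), edges = edges,
                 branch_id = branch_id, endpoints = endpoints, inlet = inlet),
            class = "centerline_network")
}

#' @export
print.centerline_network <- function(x, ...) {
  cat("<centerline_network> ", nrow(x$points), " points, ",
      nrow(x$edges), " edges, ", length(x$endpoints), " endpoints, ",
      length(unique(x$branch_id)), " branches\n", sep = "")
  invisible(x)
}

#' Serialize a centerline network to JSON
#' @param net a `centerline_network`.
#' @param path output path.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(
    points = unname(as.data.frame(net$points)),
    radius = net$radius,
    edges = unname(as.data.frame(net$edges)),
    branch_id = net$branch_id,
    endpoints = net$endpoints,
    inlet = net$inlet), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a centerline network as VTP-style XML polydata
#'
#' ASCII VTK PolyData (`.vtp`) with the network points, per-point
#' inscribed radius and branch id, and one polyline cell per graph edge.
#' @param net a `centerline_network`.
#' @param path output path.
#' @export
write_network_vtp <- function(net, path) {
  np <- nrow(net$points); ne <- nrow(net$edges)
  num <- function(x) paste(format(x, trim = TRUE, digits = 10),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfLines="%d">', np, ne))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(as.vector(t(net$points))))
  w('        </DataArray>')
  w('      </Points>')
  w('      <PointData Scalars="radius">')
  w('        <DataArray type="Float64" Name="radius" format="ascii">')
  w("          ", num(net$radius))
  w('        </DataArray>')
  if (!is.null(net$branch_id)) {
    w('        <DataArray type="Int32" Name="branch_id" format="ascii">')
    w("          ", num(net$branch_id))
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <Lines>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", num(as.vector(t(net$edges)) - 1L))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", num(seq_len(ne) * 2L))
  w('        </DataArray>')
  w('      </Lines>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nn <- function(x) if (length(x)) x else NULL
  centerline_network(as.matrix(j$points), j$radius, as.matrix(j$edges),
                     branch_id = nn(j$branch_id),
                     endpoints = nn(j$endpoints), inlet = nn(j$inlet))
}
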