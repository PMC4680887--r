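#' Build the consortium-map plot specification
#'
#' Pure function assembling everything the renderer needs: 3D coordinates,
#' sphere radii proportional to log10 relative abundance (two abundance
#' decades differ by a fixed radius increment, not a 100-fold size ratio),
#' consortium colours, and bonds for significant positive interactions with
#' widths scaling linearly with interaction strength.
#'
#' Radii: `raw = log10(abundance / min positive abundance) + 1`, then
#' linearly normalized to `[0.2, 1]` (zero-abundance OTUs get the minimum
#' radius, with a warning). Bond widths: `|c|` mapped linearly to
#' `[0.5, 3]`; the strongest bond gets 3 (a single bond is drawn at 3).
#'
#' @param embedding an [nmds()] result.
#' @param assignment a [detect_consortia()] result (or `NULL`: all gray).
#' @param mean_abundances per-OTU mean relative abundance (named or in
#'   coordinate order).
#' @param interactions optional [significant_positive_interactions()] table.
#' @param labels draw OTU labels (default `TRUE`).
#' @return object of class `plot_spec`.
#' @export
build_plot_spec <- function(embedding, assignment = NULL, mean_abundances,
                            interactions = NULL, labels = TRUE) {
  stopifnot(inherits(embedding, "nmds_embedding"))
  xyz <- embedding$coordinates
  ids <- rownames(xyz)
  ab <- mean_abundances
  if (!is.null(names(ab))) ab <- ab[ids]
  if (length(ab) != nrow(xyz))
    stop("mean_abundances must cover every embedded OTU")
  if (any(ab == 0)) warning("OTU(s) with zero mean abundance drawn at minimum radius")
  min_pos <- min(ab[ab > 0])
  raw <- ifelse(ab > 0, log10(ab / min_pos) + 1, 0)
  rng <- range(raw)
  radii <- if (diff(rng) == 0) rep(1, length(raw)) else
    0.2 + 0.8 * (raw - rng[1L]) / diff(rng)

  # first three consortia keep the classic yellow/blue/red; later groups
  # come from a colourblind-safe cycle
  palette <- c("#E6C700", "#1F77B4", "#D62728",
               "#009E73", "#CC79A7", "#56B4E9", "#E69F00", "#0072B2")
  colors <- rep("#999999", length(ids))
  if (!is.null(assignment)) {
    mem <- assignment$membership[ids]
    has <- !is.na(mem)
    colors[has] <- palette[(mem[has] - 1L) %% length(palette) + 1L]
  }

  bonds <- NULL
  if (!is.null(interactions) && nrow(interactions)) {
    if (!all(c(interactions$otu_i, interactions$otu_j) %in% ids))
      stop("interaction table references OTUs absent from the embedding")
    s <- interactions$strength
    widths <- if (length(s) == 1L || diff(range(s)) == 0) {
      rep(3, length(s))
    } else {
      0.5 + 2.5 * (s - min(s)) / (max(s) - min(s))
    }
    bonds <- data.frame(otu_i = interactions$otu_i, otu_j = interactions$otu_j,
                        strength = s, width = widths)
  }
  structure(
    list(coordinates = xyz, radii = stats::setNames(radii, ids),
         colors = stats::setNames(colors, ids), bonds = bonds,
         labels = if (labels) ids else NULL),
    class = "plot_spec"
  )
}

# fixed-camera orthographic projection of 3D points to the plotting plane
project_3d <- function(xyz, azimuth = 35, elevation = 20) {
  a <- azimuth * pi / 180; e <- elevation * pi / 180
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(e), -sin(e), 0, sin(e), cos(e)), 3, 3, byrow = TRUE)
  rot <- xyz %*% t(rz) %*% t(rx)
  list(x = rot[, 1L], y = rot[, 3L], depth = rot[, 2L])
}

#' Render a consortium map to file
#'
#' Draws the 3D consortium map through a fixed default camera (orthographic
#' projection, spheres depth-sorted so nearer OTUs occlude farther ones,
#' bonds drawn beneath the spheres). `png` and `svg` use the corresponding
#' graphics devices; `html` writes a small self-contained interactive page
#' (drag to rotate) so bonds hidden in one perspective can be inspected from
#' another.
#'
#' @param spec a [build_plot_spec()].
#' @param path output file path.
#' @param format `"png"`, `"svg"`, or `"html"`.
#' @param width,height device size in pixels (png/html) or inches (svg).
#' @return `path`, invisibly.
#' @export
render <- function(spec, path, format = c("png", "svg", "html"),
                   width = 800, height = 800) {
  stopifnot(inherits(spec, "plot_spec"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (directory does not exist): ", dir)
  if (format == "html") return(render_html(spec, path, width, height))
  if (format == "png") {
    grDevices::png(path, width = width, height = height, type = "cairo")
  } else {
    grDevices::svg(path, width = width / 100, height = height / 100)
  }
  on.exit(grDevices::dev.off())
  draw_spec(spec)
  invisible(path)
}

draw_spec <- function(spec) {
  n <- nrow(spec$coordinates)
  graphics::par(mar = c(1, 1, 2, 1))
  if (n == 0) {
    graphics::plot.new()
    graphics::title("consortium map (empty)")
    return(invisible(NULL))
  }
  pr <- project_3d(spec$coordinates)
  lim <- range(c(pr$x, pr$y))
  lim <- lim + c(-0.15, 0.15) * max(diff(lim), 1e-9)
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "consortium map")
  ids <- rownames(spec$coordinates)
  if (!is.null(spec$bonds) && nrow(spec$bonds)) {
    for (k in seq_len(nrow(spec$bonds))) {
      i <- match(spec$bonds$otu_i[k], ids)
      j <- match(spec$bonds$otu_j[k], ids)
      graphics::segments(pr$x[i], pr$y[i], pr$x[j], pr$y[j],
                         col = "#3B6FB6", lwd = spec$bonds$width[k])
    }
  }
  ord <- order(pr$depth)                       # far spheres first
  scale <- 0.06 * diff(lim)
  graphics::symbols(pr$x[ord], pr$y[ord],
                    circles = spec$radii[ord] * scale,
                    inches = FALSE, add = TRUE,
                    bg = spec$colors[ord], fg = "grey30")
  if (!is.null(spec$labels))
    graphics::text(pr$x, pr$y, labels = spec$labels, cex = 0.7, pos = 3)
  invisible(NULL)
}

render_html <- function(spec, path, width, height) {
  data <- jsonlite::toJSON(list(
    ids = rownames(spec$coordinates),
    xyz = unname(as.matrix(spec$coordinates)),
    radii = unname(spec$radii),
    colors = unname(spec$colors),
    bonds = if (is.null(spec$bonds)) list() else
      lapply(seq_len(nrow(spec$bonds)), function(k) list(
        i = match(spec$bonds$otu_i[k], rownames(spec$coordinates)) - 1L,
        j = match(spec$bonds$otu_j[k], rownames(spec$coordinates)) - 1L,
        width = spec$bonds$width[k])),
    labels = !is.null(spec$labels)
  ), auto_unbox = TRUE, digits = NA)
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>consortium map</title></head>",
    "<body style='margin:0'><canvas id='c' width='", width, "' height='", height,
    "'></canvas><script>\nvar D=", data, ";\n",
    "var cv=document.getElementById('c'),cx=cv.getContext('2d');",
    "var az=0.6,el=0.35,drag=false,px=0,py=0;",
    "function draw(){cx.clearRect(0,0,cv.width,cv.height);",
    "var ca=Math.cos(az),sa=Math.sin(az),ce=Math.cos(el),se=Math.sin(el);",
    "var P=D.xyz.map(function(p){var x=ca*p[0]-sa*p[1],y=sa*p[0]+ca*p[1],z=p[2];",
    "return[x,ce*z-se*y,se*z+ce*y];});",
    "var ext=0;P.forEach(function(p){ext=Math.max(ext,Math.abs(p[0]),Math.abs(p[1]));});",
    "ext=ext||1;var s=0.4*Math.min(cv.width,cv.height)/ext;",
    "function sx(p){return cv.width/2+s*p[0];}function sy(p){return cv.height/2-s*p[1];}",
    "D.bonds.forEach(function(b){cx.strokeStyle='#3B6FB6';cx.lineWidth=b.width;",
    "cx.beginPath();cx.moveTo(sx(P[b.i]),sy(P[b.i]));cx.lineTo(sx(P[b.j]),sy(P[b.j]));cx.stroke();});",
    "var ord=P.map(function(p,i){return i;}).sort(function(a,b){return P[a][2]-P[b][2];});",
    "ord.forEach(function(i){cx.beginPath();cx.arc(sx(P[i]),sy(P[i]),D.radii[i]*0.05*s,0,2*Math.PI);",
    "cx.fillStyle=D.colors[i];cx.fill();cx.strokeStyle='#444';cx.lineWidth=1;cx.stroke();",
    "if(D.labels){cx.fillStyle='#222';cx.font='12px sans-serif';",
    "cx.fillText(D.ids[i],sx(P[i])+4,sy(P[i])-4);}});}",
    "cv.onmousedown=function(e){drag=true;px=e.clientX;py=e.clientY;};",
    "window.onmouseup=function(){drag=false;};",
    "window.onmousemove=function(e){if(!drag)return;az+=(e.clientX-px)*0.01;",
    "el+=(e.clientY-py)*0.01;px=e.clientX;py=e.clientY;draw();};",
    "draw();\n</script></body></html>")
  writeLines(html, path)
  invisible(path)
}
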