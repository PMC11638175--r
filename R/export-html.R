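#' Export an interactive network page
#'
#' Writes a single self-contained HTML file: the node-link data is
#' embedded as JSON (`<script type="application/json" id="network-data">`)
#' and rendered by a small inline force-directed canvas renderer (drag to
#' reposition, hover for edge importances). No network fetches, no
#' external assets.
#'
#' Nodes are the union of TFs and targets with a `role` attribute
#' (`"tf"`, `"target"`, or `"both"`); edges carry their importance.
#'
#' @param t An `edge_table`.
#' @param path Output HTML path.
#' @param top_n Optional cap: only the strongest `top_n` edges are drawn.
#' @return `path`, invisibly.
#' @export
export_html <- function(t, path, top_n = NULL) {
  if (!is.null(top_n)) t <- rank_edges(t, top_n = top_n)
  tf_set <- unique(t$tf)
  tg_set <- unique(t$target)
  all_nodes <- unique(c(tf_set, tg_set))
  nodes <- lapply(all_nodes, function(id) {
    role <- if (id %in% tf_set && id %in% tg_set) "both"
      else if (id %in% tf_set) "tf" else "target"
    list(id = id, role = role)
  })
  edges <- lapply(seq_len(nrow(t)), function(i)
    list(tf = t$tf[i], target = t$target[i], importance = t$importance[i]))
  payload <- jsonlite::toJSON(list(nodes = nodes, edges = edges),
                              auto_unbox = TRUE, digits = NA)
  empty_note <- if (nrow(t) == 0L)
    "<p class=\"note\">no edges to display</p>" else ""
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>Regulatory network</title>\n",
    "<style>body{font-family:sans-serif;margin:1em}canvas{border:1px solid #ccc}",
    ".note{color:#666}#info{min-height:1.2em;color:#333}</style>\n</head>\n<body>\n",
    "<h1>TF &#8594; target network</h1>\n", empty_note,
    "<div id=\"info\"></div>\n<canvas id=\"net\" width=\"900\" height=\"600\"></canvas>\n",
    "<script type=\"application/json\" id=\"network-data\">", payload, "</script>\n",
    "<script>\n", network_renderer_js(), "\n</script>\n</body>\n</html>\n")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(html, con, sep = "")
  invisible(path)
}

# Inline renderer: simple spring embedding + drag + hover readout.
network_renderer_js <- function() {
  paste(
    "var data = JSON.parse(document.getElementById('network-data').textContent);",
    "var cv = document.getElementById('net'), cx = cv.getContext('2d');",
    "var W = cv.width, H = cv.height;",
    "var nodes = data.nodes.map(function(n, i) {",
    "  var a = 2 * Math.PI * i / Math.max(1, data.nodes.length);",
    "  return {id: n.id, role: n.role, x: W/2 + 200*Math.cos(a),",
    "          y: H/2 + 200*Math.sin(a), vx: 0, vy: 0};",
    "});",
    "var byId = {}; nodes.forEach(function(n){ byId[n.id] = n; });",
    "var maxImp = 1e-12;",
    "data.edges.forEach(function(e){ if (e.importance > maxImp) maxImp = e.importance; });",
    "function step() {",
    "  for (var i = 0; i < nodes.length; i++) for (var j = i+1; j < nodes.length; j++) {",
    "    var a = nodes[i], b = nodes[j], dx = a.x-b.x, dy = a.y-b.y;",
    "    var d2 = dx*dx + dy*dy + 0.01, f = 2000 / d2;",
    "    a.vx += f*dx; a.vy += f*dy; b.vx -= f*dx; b.vy -= f*dy;",
    "  }",
    "  data.edges.forEach(function(e){",
    "    var a = byId[e.tf], b = byId[e.target];",
    "    var dx = b.x-a.x, dy = b.y-a.y, d = Math.sqrt(dx*dx+dy*dy)+0.01;",
    "    var f = 0.002 * (d - 120);",
    "    a.vx += f*dx; a.vy += f*dy; b.vx -= f*dx; b.vy -= f*dy;",
    "  });",
    "  nodes.forEach(function(n){",
    "    if (n !== dragged) { n.x += Math.max(-5, Math.min(5, n.vx));",
    "      n.y += Math.max(-5, Math.min(5, n.vy)); }",
    "    n.vx *= 0.6; n.vy *= 0.6;",
    "    n.x = Math.max(15, Math.min(W-15, n.x));",
    "    n.y = Math.max(15, Math.min(H-15, n.y));",
    "  });",
    "}",
    "function draw() {",
    "  cx.clearRect(0, 0, W, H);",
    "  data.edges.forEach(function(e){",
    "    var a = byId[e.tf], b = byId[e.target];",
    "    cx.strokeStyle = 'rgba(100,100,100,0.6)';",
    "    cx.lineWidth = 0.5 + 3 * e.importance / maxImp;",
    "    cx.beginPath(); cx.moveTo(a.x, a.y); cx.lineTo(b.x, b.y); cx.stroke();",
    "  });",
    "  nodes.forEach(function(n){",
    "    cx.fillStyle = n.role === 'target' ? '#4a90d9' : '#d94a4a';",
    "    cx.beginPath(); cx.arc(n.x, n.y, n.role === 'target' ? 6 : 9, 0, 2*Math.PI); cx.fill();",
    "    cx.fillStyle = '#000'; cx.font = '10px sans-serif';",
    "    cx.fillText(n.id, n.x + 10, n.y + 3);",
    "  });",
    "}",
    "var dragged = null;",
    "function nodeAt(x, y) {",
    "  for (var i = 0; i < nodes.length; i++) {",
    "    var dx = nodes[i].x - x, dy = nodes[i].y - y;",
    "    if (dx*dx + dy*dy < 144) return nodes[i];",
    "  } return null;",
    "}",
    "cv.addEventListener('mousedown', function(ev){",
    "  var r = cv.getBoundingClientRect();",
    "  dragged = nodeAt(ev.clientX - r.left, ev.clientY - r.top);",
    "});",
    "cv.addEventListener('mousemove', function(ev){",
    "  var r = cv.getBoundingClientRect(), x = ev.clientX-r.left, y = ev.clientY-r.top;",
    "  if (dragged) { dragged.x = x; dragged.y = y; }",
    "  var n = nodeAt(x, y), info = document.getElementById('info');",
    "  if (n) {",
    "    var outs = data.edges.filter(function(e){ return e.tf === n.id; });",
    "    info.textContent = n.id + ' (' + n.role + '), outgoing edges: ' + outs.length;",
    "  } else info.textContent = '';",
    "});",
    "window.addEventListener('mouseup', function(){ dragged = null; });",
    "var ticks = 0;",
    "function loop() { step(); draw(); if (++ticks < 600 || dragged) ;",
    "  requestAnimationFrame(loop); }",
    "if (nodes.length > 0) loop(); else draw();",
    sep = "\n")
}
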