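# Structured annular HEX8 mesh between two surfaces z_bottom(r, phi) and
# z_top(r, phi). A small inner radius avoids the degenerate polar apex that
# collapsed hexes would otherwise create.
build_hex_mesh <- function(z_bottom, z_top, r_inner, r_outer,
                           rings, sectors, layers) {
  r <- seq(r_inner, r_outer, length.out = rings + 1)
  phi <- seq(0, 2 * pi, length.out = sectors + 1)[seq_len(sectors)]
  lev <- seq(0, 1, length.out = layers + 1)
  nid <- function(i, j, l) {
    ((l - 1) * sectors + (j - 1)) * (rings + 1) + i
  }
  nodes <- matrix(0, (rings + 1) * sectors * (layers + 1), 3)
  for (l in seq_len(layers + 1)) {
    for (j in seq_len(sectors)) {
      zb <- z_bottom(r, phi[j])
      zt <- z_top(r, phi[j])
      z <- zb + lev[l] * (zt - zb)
      ids <- nid(seq_len(rings + 1), j, l)
      nodes[ids, ] <- cbind(r * cos(phi[j]), r * sin(phi[j]), z)
    }
  }
  elems <- matrix(0L, rings * sectors * layers, 8)
  e <- 0
  for (l in seq_len(layers)) {
    for (j in seq_len(sectors)) {
      jn <- if (j == sectors) 1 else j + 1
      for (i in seq_len(rings)) {
        e <- e + 1
        elems[e, ] <- c(
          nid(i, j, l), nid(i + 1, j, l), nid(i + 1, jn, l), nid(i, jn, l),
          nid(i, j, l + 1), nid(i + 1, j, l + 1), nid(i + 1, jn, l + 1), nid(i, jn, l + 1)
        )
      }
    }
  }
  # quad facets of the bottom (l = 1) and top (l = layers + 1) skins
  skin <- function(l) {
    f <- matrix(0L, rings * sectors, 4)
    e <- 0
    for (j in seq_len(sectors)) {
      jn <- if (j == sectors) 1 else j + 1
      for (i in seq_len(rings)) {
        e <- e + 1
        f[e, ] <- c(nid(i, j, l), nid(i + 1, j, l), nid(i + 1, jn, l), nid(i, jn, l))
      }
    }
    f
  }
  list(
    nodes = nodes, elements = elems,
    bottom_facets = skin(1), top_facets = skin(layers + 1)
  )
}

#' Centroid Jacobian determinants of HEX8 elements
#'
#' Trilinear-map Jacobian evaluated at each element centroid; all values
#' must be positive for a valid (non-inverted) mesh.
#'
#' @param nodes Numeric matrix of node coordinates (n x 3).
#' @param elements Integer matrix of HEX8 connectivity (m x 8).
#' @return Numeric vector of determinants (mm^3 scale).
#' @export
hex_jacobians <- function(nodes, elements) {
  sx <- c(-1, 1, 1, -1, -1, 1, 1, -1) / 8
  sy <- c(-1, -1, 1, 1, -1, -1, 1, 1) / 8
  sz <- c(-1, -1, -1, -1, 1, 1, 1, 1) / 8
  apply(elements, 1, function(el) {
    xyz <- nodes[el, , drop = FALSE]
    J <- rbind(
      colSums(sx * xyz),
      colSums(sy * xyz),
      colSums(sz * xyz)
    )
    det(J)
  })
}

#' Write a finite-element input file for the lens-on-cornea problem
#'
#' Exports structured HEX8 meshes of the lens (between its back and front
#' surfaces) and the rigid cornea (between its two parallel spherical
#' surfaces), linear-elastic material cards (measured modulus, nu = 0.49),
#' the tear-film pressure P1 on the lens back and cornea front, the eyelid
#' pressure P2 on the lens front (ramped in from halfway through the
#' analysis step), frictional sliding contact (mu from the load case), and
#' the boundary conditions (cornea fully fixed; lens centre node held in x
#' and y) — as a FEBio-style XML input file. Pressures are written in MPa
#' (mm/N/MPa unit system). Solving is external to this package.
#'
#' @param lens A `lens_geometry`.
#' @param cornea A [cornea_model()].
#' @param material Anything [get_material()] accepts.
#' @param loads A [load_case()].
#' @param path Output `.feb` / `.xml` path.
#' @param rings,sectors,layers Structured mesh resolution per component
#'   (element count = rings x sectors x layers).
#' @param inner_radius Inner radius of the annular mesh (mm).
#' @return Invisible list with `path`, per-component element counts and the
#'   minimum centroid Jacobian.
#' @export
export_fe_model <- function(lens, cornea, material, loads = load_case(), path,
                            rings = 10, sectors = 24, layers = 2,
                            inner_radius = 0.1) {
  mat <- get_material(material)
  # lens surfaces as interpolators over the geometry grid
  z_back <- function(r, phi) approx(lens$X, lens$Zb, xout = r, rule = 2)$y
  mer <- lens$meridian_deg * pi / 180
  z_front <- function(r, phi) {
    # linear blend between the two bounding meridians
    ph <- phi %% (2 * pi)
    j1 <- findInterval(ph, mer)
    if (j1 < 1) j1 <- length(mer)
    j2 <- if (j1 == length(mer)) 1 else j1 + 1
    span <- (mer[j2] - mer[j1]) %% (2 * pi)
    wph <- if (span == 0) 0 else ((ph - mer[j1]) %% (2 * pi)) / span
    z1 <- approx(lens$X, lens$Zf[j1, ], xout = r, rule = 2)$y
    z2 <- approx(lens$X, lens$Zf[j2, ], xout = r, rule = 2)$y
    (1 - wph) * z1 + wph * z2
  }
  lens_mesh <- build_hex_mesh(
    z_back, z_front, inner_radius, lens$spec$diameter / 2, rings, sectors, layers
  )
  t_mm <- cornea$thickness_um / 1000
  rc_post <- cornea$Rc - t_mm
  r_out_cornea <- min(lens$spec$diameter / 2, 0.9 * rc_post)
  z_cfront <- function(r, phi) -(cornea$Rc - sqrt(cornea$Rc^2 - r^2))
  z_cback <- function(r, phi) -t_mm - (rc_post - sqrt(rc_post^2 - r^2))
  cornea_mesh <- build_hex_mesh(
    z_cback, z_cfront, inner_radius, r_out_cornea, rings, sectors, layers
  )
  jac <- c(
    hex_jacobians(lens_mesh$nodes, lens_mesh$elements),
    hex_jacobians(cornea_mesh$nodes, cornea_mesh$elements)
  )
  if (any(jac <= 0)) {
    abort("inverted hexahedra in the exported mesh", class = "onlens_export_error")
  }

  p1_MPa <- loads$tear_pressure_Pa * 1e-6
  p2_MPa <- loads$eyelid_pressure_Pa * 1e-6
  n_lens_nodes <- nrow(lens_mesh$nodes)
  # lens centre node: nearest to the back apex
  centre_id <- which.min(rowSums(lens_mesh$nodes^2))

  doc <- xml2::xml_new_root("febio_spec", version = "3.0")
  xml2::xml_add_child(doc, "Module", type = "solid")
  mats <- xml2::xml_add_child(doc, "Material")
  m1 <- xml2::xml_add_child(mats, "material", id = "1", name = "lens", type = "isotropic elastic")
  xml2::xml_add_child(m1, "E", format(mat$modulus, digits = 15))
  xml2::xml_add_child(m1, "v", format(mat$poisson, digits = 15))
  xml2::xml_add_child(m1, "density", "1e-9")
  m2 <- xml2::xml_add_child(mats, "material", id = "2", name = "cornea", type = "rigid body")
  xml2::xml_add_child(m2, "density", "1e-9")

  mesh <- xml2::xml_add_child(doc, "Mesh")
  add_nodes <- function(name, nodes, offset) {
    nd <- xml2::xml_add_child(mesh, "Nodes", name = name)
    for (i in seq_len(nrow(nodes))) {
      xml2::xml_add_child(nd, "node",
        paste(format(nodes[i, ], digits = 10), collapse = ","),
        id = as.character(i + offset)
      )
    }
  }
  add_elems <- function(name, elems, offset, eoffset) {
    el <- xml2::xml_add_child(mesh, "Elements", type = "hex8", name = name)
    for (i in seq_len(nrow(elems))) {
      xml2::xml_add_child(el, "elem",
        paste(elems[i, ] + offset, collapse = ","),
        id = as.character(i + eoffset)
      )
    }
  }
  add_surface <- function(name, facets, offset) {
    sf <- xml2::xml_add_child(mesh, "Surface", name = name)
    for (i in seq_len(nrow(facets))) {
      xml2::xml_add_child(sf, "quad4",
        paste(facets[i, ] + offset, collapse = ","),
        id = as.character(i)
      )
    }
  }
  add_nodes("lens_nodes", lens_mesh$nodes, 0)
  add_nodes("cornea_nodes", cornea_mesh$nodes, n_lens_nodes)
  add_elems("lens_elems", lens_mesh$elements, 0, 0)
  add_elems("cornea_elems", cornea_mesh$elements, n_lens_nodes, nrow(lens_mesh$elements))
  add_surface("lens_back", lens_mesh$bottom_facets, 0)
  add_surface("lens_front", lens_mesh$top_facets, 0)
  add_surface("cornea_front", cornea_mesh$top_facets, n_lens_nodes)
  ns <- xml2::xml_add_child(mesh, "NodeSet", name = "lens_centre")
  xml2::xml_add_child(ns, "node", id = as.character(centre_id))

  dom <- xml2::xml_add_child(doc, "MeshDomains")
  xml2::xml_add_child(dom, "SolidDomain", name = "lens_elems", mat = "lens")
  xml2::xml_add_child(dom, "SolidDomain", name = "cornea_elems", mat = "cornea")

  bnd <- xml2::xml_add_child(doc, "Boundary")
  bc <- xml2::xml_add_child(bnd, "bc", type = "fix", node_set = "lens_centre")
  xml2::xml_add_child(bc, "dofs", "x,y")

  rig <- xml2::xml_add_child(doc, "Rigid")
  rc <- xml2::xml_add_child(rig, "rigid_constraint", name = "fix_cornea", type = "fix")
  xml2::xml_add_child(rc, "rb", "2")
  xml2::xml_add_child(rc, "dofs", "Rx,Ry,Rz,Ru,Rv,Rw")

  lds <- xml2::xml_add_child(doc, "Loads")
  add_pressure <- function(name, surface, value, lc) {
    sl <- xml2::xml_add_child(lds, "surface_load", name = name, type = "pressure", surface = surface)
    xml2::xml_add_child(sl, "pressure", format(value, digits = 15), lc = as.character(lc))
    xml2::xml_add_child(sl, "linear", "0")
  }
  add_pressure("tear_lens_back", "lens_back", p1_MPa, 1)
  add_pressure("tear_cornea_front", "cornea_front", p1_MPa, 1)
  add_pressure("eyelid_lens_front", "lens_front", p2_MPa, 2)

  cnt <- xml2::xml_add_child(doc, "Contact")
  cs <- xml2::xml_add_child(cnt, "contact",
    type = "sliding-elastic",
    surface_pair = "lens_cornea"
  )
  xml2::xml_add_child(cs, "fric_coeff", format(loads$friction, digits = 15))
  xml2::xml_add_child(cs, "two_pass", "0")
  sp <- xml2::xml_add_child(mesh, "SurfacePair", name = "lens_cornea")
  xml2::xml_add_child(sp, "primary", "cornea_front") # rigid master surface
  xml2::xml_add_child(sp, "secondary", "lens_back")

  ldat <- xml2::xml_add_child(doc, "LoadData")
  lc1 <- xml2::xml_add_child(ldat, "load_controller", id = "1", type = "loadcurve")
  xml2::xml_add_child(lc1, "points", "0,0;1,1")
  # eyelid pressure is applied incrementally from halfway through the step
  lc2 <- xml2::xml_add_child(ldat, "load_controller", id = "2", type = "loadcurve")
  xml2::xml_add_child(lc2, "points", "0,0;0.5,0;1,1")

  xml2::write_xml(doc, path)
  invisible(list(
    path = path,
    n_lens_elements = nrow(lens_mesh$elements),
    n_cornea_elements = nrow(cornea_mesh$elements),
    min_jacobian = min(jac)
  ))
}
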