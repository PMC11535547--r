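# Shared fixtures, built once per test run. The network and reference
# patient are deterministic; tests that perturb them copy first.

ra_net <- ra_network()
ra_ref <- reference_patient(ra_net)

# A network with every regulatory edge (and the essential gate) removed:
# the decoupled model with closed-form steady states.
decoupled_network <- function() {
  net <- ra_net
  net$regulation <- net$regulation[0, ]
  net$essential <- net$essential[0, ]
  net
}

# Independent slow-path evaluation of the cell/mediator derivatives using
# only the exported regulation primitives (hill, aggregate_effects,
# rate_factor, essential_gate); oracle for the compiled right-hand side.
oracle_rhs <- function(net, patient, state) {
  p <- patient$params
  conc <- state$mediator_conc
  dens <- state$cell_density
  edge_list <- function(rows) {
    lapply(seq_len(nrow(rows)), function(i) {
      regulatory_edge(rows$regulator[i], "shared", rows$sign[i],
                      p[[rows$param[i]]], rows$km[i], rows$slope[i])
    })
  }
  fac <- function(rows) {
    if (!nrow(rows)) return(1)
    rate_factor(aggregate_effects(edge_list(rows), conc, net$policy))
  }
  ed <- net$regulation
  dcell <- sapply(net$cells, function(cl) {
    prolif <- p[[rasim:::kg_name(cl)]] *
      fac(ed[ed$process == "prolif" & ed$cell == cl, ])
    influx <- p[[rasim:::kin_name(cl)]] *
      fac(ed[ed$process == "influx" & ed$cell == cl, ])
    deg <- p[[rasim:::kdeg_name(cl)]] * dens[[cl]] *
      fac(ed[ed$process == "deg" & ed$cell == cl, ])
    prolif + influx - deg
  })
  fdiff <- p[["kdiff_BCells_PlasmaCells"]] * fac(ed[ed$process == "diff", ]) *
    dens[[net$differentiation$source]]
  dcell[[net$differentiation$source]] <-
    dcell[[net$differentiation$source]] - fdiff
  dcell[[net$differentiation$target]] <-
    dcell[[net$differentiation$target]] + fdiff
  dmed <- sapply(net$mediators, function(md) {
    if (md == net$cam$mediator) {
      e <- dens[[net$cam$driver]]
      tgt <- p[[rasim:::f_name(md)]] * net$cam$level *
        e^net$cam$slope / (e^net$cam$slope + net$cam$km^net$cam$slope)
      return(net$cam$k_relax * (tgt - conc[[md]]))
    }
    rows <- net$secretion[net$secretion$mediator == md, ]
    flux <- 0
    for (i in seq_len(nrow(rows))) {
      f <- p[[rasim:::ksec_name(md, rows$cell[i])]] * dens[[rows$cell[i]]] *
        fac(ed[ed$process == "sec" & ed$mediator == md &
                 ed$cell == rows$cell[i], ])
      ess <- net$essential[net$essential$secreted == md &
                             net$essential$cell == rows$cell[i], ]
      if (nrow(ess))
        f <- essential_gate(f, conc[[ess$mediator]], ess$km_gate, ess$slope)
      flux <- flux + f
    }
    p[[rasim:::f_name(md)]] * flux - p[[rasim:::clr_name(md)]] * conc[[md]]
  })
  c(dcell, dmed)
}
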