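# Canonical drive sequences for the four circuit/drive model variants.
# Times are ms post stimulus onset; weights are peak synaptic conductances
# in uS keyed by <target class>_<receptor>.  Weight values are the package
# calibration against the shipped synthetic targets; timing parameters are
# fixed by the study design.

variants:
  preferred:
    undetected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.2
        n_spikes: 2
        weights: &prox1_w
          L23_PN_ampa: 0.02
          L23_PN_nmda: 0.002
          L5_PN_ampa: 0.01
          L5_PN_nmda: 0.002
          L23_basket_ampa: 0.0005
          L5_basket_ampa: 0.0003
      - name: dist1
        kind: distal
        mean_time: 84.3
        sd_time: 15.1
        n_spikes: 1
        weights: &dist1_w
          L23_PN_ampa: 0.01
          L23_PN_nmda: 0.001
          L5_PN_ampa: 0.02
          L5_PN_nmda: 0.01
          L23_basket_ampa: 0.003
    detected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.2
        n_spikes: 2
        weights: *prox1_w
      - name: dist1
        kind: distal
        mean_time: 84.3
        sd_time: 15.1
        n_spikes: 1
        weights: *dist1_w
      - name: dist2
        kind: distal
        mean_time: 169.3
        sd_time: 50.4
        n_spikes: 1
        weights: &dist2_w
          L23_PN_ampa: 0.005
          L23_PN_nmda: 0.002
          L5_PN_ampa: 0.03
          L5_PN_nmda: 0.02
          L23_basket_ampa: 0.002
    frozen_detected: [prox1, dist1]

  perisomatic_inhibition:
    perisomatic_gabab_factor: 2
    undetected:
      - name: prox1
        kind: proximal
        mean_time: 36
        sd_time: 25
        n_spikes: 2
        weights: *prox1_w
      - name: dist1
        kind: distal
        mean_time: 84.3
        sd_time: 15.1
        n_spikes: 1
        weights: *dist1_w
    detected:
      - name: prox1
        kind: proximal
        mean_time: 36
        sd_time: 25
        n_spikes: 2
        weights: *prox1_w
      - name: dist1
        kind: distal
        mean_time: 84.3
        sd_time: 15.1
        n_spikes: 1
        weights: *dist1_w
      - name: prox2
        kind: proximal
        mean_time: 169.3
        sd_time: 50.4
        n_spikes: 1
        weights:
          L23_PN_ampa: 0.002
          L5_PN_ampa: 0.002
          L23_basket_ampa: 0.01
          L5_basket_ampa: 0.01
    frozen_detected: [prox1, dist1]

  reduced:
    undetected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.3
        n_spikes: 2
        weights: *prox1_w
    detected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.3
        n_spikes: 2
        weights: *prox1_w
      - name: dist1
        kind: distal
        mean_time: 154
        sd_time: 55.1
        n_spikes: 1
        weights: *dist2_w
    frozen_detected: [prox1]

  prox_dist_prox:
    undetected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.3
        n_spikes: 2
        weights: *prox1_w
    detected:
      - name: prox1
        kind: proximal
        mean_time: 47.8
        sd_time: 13.3
        n_spikes: 2
        weights: *prox1_w
      - name: dist1
        kind: distal
        mean_time: 154
        sd_time: 55.1
        n_spikes: 1
        weights: *dist2_w
      - name: prox2
        kind: proximal
        mean_time: 395.4
        sd_time: 20
        n_spikes: 1
        weights:
          L23_PN_ampa: 0.005
          L23_PN_nmda: 0.0005
          L5_PN_ampa: 0.003
          L23_basket_ampa: 0.0005
          L5_basket_ampa: 0.0005
    frozen_detected: [prox1]
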