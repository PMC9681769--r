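# Default electrostatic-sorter routing model (versioned defaults).
# Calibrated from the P=0.5 inflection anchor (27.4 V_RMS, 51.5 nL/s, 1 nL)
# and the efficient-regime anchor P=0.99 at (40 V_RMS, 60 nL/s), with the
# voltage main effect fixed at 0.15/V_RMS and the flow-slope sign change at
# 20 V_RMS. See calibrateRoutingModel().
version: 1
beta0: -5.3689097263234711
betaV: 0.14999999999999999
betaQ: -0.066067159607634346
betaVQ: 0.0033033579803817175
betaVol: -3
passive_fidelity_80: 0.995
passive_fidelity_60: 0.992
v_low: 27.4
q_low: 51.5
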