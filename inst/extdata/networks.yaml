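# Cluster-to-network merging for the 10-cluster cerebellar solution:
# the three executive clusters (7-9) merge into one network, the two limbic
# clusters (5, 6) into another, giving 7 networks overall.
networks:
  - {cluster: 1, network: sensorimotor}
  - {cluster: 2, network: directed_attention}
  - {cluster: 3, network: divided_attention}
  - {cluster: 4, network: language}
  - {cluster: 5, network: limbic}
  - {cluster: 6, network: limbic}
  - {cluster: 7, network: executive}
  - {cluster: 8, network: executive}
  - {cluster: 9, network: executive}
  - {cluster: 10, network: mentalizing}
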