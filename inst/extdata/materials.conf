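name: bone
elements: Ca P O N C H
fractions: 0.09863 0.05918 0.31413 0.04946 0.17861 0.3
density: 1.41

name: mineral
elements: H O P Ca
fractions: 2 26 6 10
density: 1.01

name: collagen
elements: H C N O
fractions: 0.49514 0.31554 0.08738 0.10194
density: 0.41
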