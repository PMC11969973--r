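{"u0":0.16945587665312,"feed01":1.62645093711217,"feed02":1.72371040333816,"feed03":1.18810660754699,"feed04":1.45395384023957,"feed05":1.0544499680573,"feed06":0.764053229399105,"feed07":0.819910745668408,"feed08":1.40771430828748,"feed09":0.941291114174066,"feed10":0.403109031294459,"feed11":1.01291016823392,"feed12":0.433594024451529,"feed13":1.02833179850153,"feed14":1.72811687213339,"feed15":0.746762234729118,"feed16":1.46688674280107,"cpg1":1.67657328570053,"cpg2":1.03870365092856,"cpg3":1.59674886439356,"cpg4":1.82392676350284,"cpg5":1.17894367214004,"cpg6":1.02132772351303,"cpg7":2.3367670199298,"cpg8":2.1645206180512,"cpg9":1.9619662883797,"pos01":13.1267842387758,"pos02":8.21475691240861,"pos03":0.851624922319906,"pos04":2.20650011231603,"pos05":0.415339218971107,"pos06":22.6184252046972,"pos07":25.3574652490229,"pos08":5.70596839887119,"pos09":7.13312062341275,"pos10":6.04277658109983,"pos11":3.85364326894345,"pos12":14.1943479617289,"pos13":3.76399994505061,"pos14":13.7867893991014,"pos15":20.1776370402436,"pos16":13.3893661007708,"pos17":4.58463242927724,"pos18":10.8045716209293,"pos19":26.6328381296906,"pos20":22.1327324459576,"pos21":2.82816621744211,"pos22":8.48777727966225,"pos23":2.60749535671589}
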