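{"atoms":[{"element":"C","mass":12.011,"x":1.39,"y":0,"z":0},{"element":"C","mass":12.011,"x":0.695,"y":1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":-0.695,"y":1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":-1.39,"y":1.70225905081482e-16,"z":0},{"element":"C","mass":12.011,"x":-0.695000000000001,"y":-1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":0.695,"y":-1.20377531126037,"z":0},{"element":"H","mass":1.008,"x":1.235,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":-1.235,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":-1.235,"y":-2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":1.235,"y":-2.13908274734756,"z":0},{"element":"N","mass":14.007,"x":5.65,"y":0,"z":0},{"element":"C","mass":12.011,"x":4.955,"y":1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":3.565,"y":1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":2.87,"y":1.70225905081482e-16,"z":0},{"element":"C","mass":12.011,"x":3.565,"y":-1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":4.955,"y":-1.20377531126037,"z":0},{"element":"H","mass":1.008,"x":5.495,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":3.025,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":3.025,"y":-2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":5.495,"y":-2.13908274734756,"z":0},{"element":"C","mass":12.011,"x":-2.87,"y":0,"z":0},{"element":"C","mass":12.011,"x":-3.565,"y":1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":-4.955,"y":1.20377531126037,"z":0},{"element":"N","mass":14.007,"x":-5.65,"y":1.70225905081482e-16,"z":0},{"element":"C","mass":12.011,"x":-4.955,"y":-1.20377531126037,"z":0},{"element":"C","mass":12.011,"x":-3.565,"y":-1.20377531126037,"z":0},{"element":"H","mass":1.008,"x":-3.025,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":-5.495,"y":2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":-5.495,"y":-2.13908274734756,"z":0},{"element":"H","mass":1.008,"x":-3.025,"y":-2.13908274734756,"z":0}],"bonds":[[0,1],[0,5],{"i":0,"j":13,"r0":1.48},[1,2],[1,6],[2,3],[2,7],[3,4],{"i":3,"j":20,"r0":1.48},[4,5],[4,8],[5,9],[10,11],[10,15],[11,12],[11,16],[12,13],[12,17],[13,14],[14,15],[14,18],[15,19],[20,21],[20,25],[21,22],[21,26],[22,23],[22,27],[23,24],[24,25],[24,28],[25,29]]}
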